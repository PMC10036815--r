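#' Read a delimited spectra table
#'
#' The on-disk format is plain delimited text (comma by default, tab
#' accepted) with header
#' `sample_id,species,location,replicate,set,density,<wavelength...>`,
#' wavelength column names being the grid values in nm. A `mode` comment
#' line (`# mode: reflectance`) written by [write_spectra()] is honoured;
#' absent that, reflectance is assumed.
#'
#' @param path file to read.
#' @param sep field separator, `","` or `"\t"`.
#' @return A [spectra_dataset()].
#' @export
read_spectra <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  mode <- "reflectance"
  skip <- 0L
  if (startsWith(first, "# mode:")) {
    mode <- trimws(sub("# mode:", "", first, fixed = TRUE))
    skip <- 1L
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep, skip = skip,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  meta_cols <- c("sample_id", "species", "location", "replicate", "set", "density")
  missing_cols <- setdiff(meta_cols, names(tab))
  if (length(missing_cols))
    stop("missing metadata columns: ", paste(missing_cols, collapse = ", "))
  wl_names <- setdiff(names(tab), meta_cols)
  wavelengths <- suppressWarnings(as.numeric(wl_names))
  if (any(is.na(wavelengths)))
    stop("non-numeric wavelength column names: ",
         paste(wl_names[is.na(wavelengths)], collapse = ", "))
  if (any(diff(wavelengths) <= 0))
    stop("wavelength header is not strictly increasing")
  spec_raw <- tab[, wl_names, drop = FALSE]
  bad_rows <- which(!vapply(seq_len(nrow(spec_raw)), function(i) {
    v <- suppressWarnings(as.numeric(unlist(spec_raw[i, ], use.names = FALSE)))
    !anyNA(v)
  }, TRUE))
  if (length(bad_rows))
    stop("non-numeric spectral values in row(s): ",
         paste(bad_rows, collapse = ", "))
  if (anyNA(suppressWarnings(as.numeric(tab$density))))
    stop("non-numeric density in row(s): ",
         paste(which(is.na(suppressWarnings(as.numeric(tab$density)))),
               collapse = ", "))
  key <- paste(tab$sample_id, tab$replicate)
  if (anyDuplicated(key))
    stop("duplicate sample_id + replicate: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  spectra <- as.matrix(sapply(spec_raw, as.numeric))
  if (nrow(tab) == 1L) spectra <- matrix(spectra, nrow = 1L)
  spectra_dataset(
    wavelengths = wavelengths, spectra = spectra,
    density = tab$density, sample_id = tab$sample_id,
    species = tab$species, location = tab$location,
    replicate = tab$replicate, mode = mode, set = tab$set
  )
}

#' Write a spectra dataset as delimited text
#'
#' @param ds a [spectra_dataset()].
#' @param path destination file.
#' @param sep field separator.
#' @param digits significant digits retained for spectral values; the
#'   default (17) makes write/read round trips exact to double precision.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path, sep = ",", digits = 17L) {
  stopifnot(inherits(ds, "spectra_dataset"))
  header <- c("sample_id", "species", "location", "replicate", "set",
              "density", format(ds$wavelengths, trim = TRUE, digits = 15L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# mode: ", ds$mode), con)
  writeLines(paste(header, collapse = sep), con)
  m <- ds$meta
  for (i in seq_len(nrow(ds$spectra))) {
    row <- c(m$sample_id[i], m$species[i], m$location[i], m$replicate[i],
             m$set[i], format(m$density[i], digits = digits, trim = TRUE),
             format(ds$spectra[i, ], digits = digits, trim = TRUE))
    writeLines(paste(row, collapse = sep), con)
  }
  invisible(path)
}
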