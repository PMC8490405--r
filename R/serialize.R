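# Model container format, version 1. A single binary file:
#   bytes 0..7   : magic "ARDCAv1\n"
#   bytes 8..11  : little-endian int32, byte length of the JSON header
#   header       : UTF-8 JSON with L, q, alphabet, order (0-based perm),
#                  order_label, meta, and the two array lengths
#   payload      : little-endian float64 arrays, h then J
# h layout: site-major, q values per model position. J layout: for model
# positions i = 2..L in turn, the q x q x (i-1) block in column-major
# order (target symbol a fastest, then context symbol b, then context
# position j). The format is deliberately free of timestamps so that
# save -> load -> save is byte-identical.

ardca_magic <- function() charToRaw("ARDCAv1\n")

#' Save / load an autoregressive model
#'
#' The file holds a JSON metadata header (dimensions, alphabet, site
#' order, training provenance, format version) followed by flat
#' little-endian float64 parameter arrays; the round trip preserves every
#' parameter bit-exactly. Loading verifies the format version and that
#' the array lengths match the metadata, and names the offending field
#' otherwise.
#'
#' @param model An \code{"ardca"} model.
#' @param path File path.
#' @return \code{load_model}: the restored \code{"ardca"} model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ardca"))
  L <- model$L; q <- model$q
  hvec <- as.vector(t(model$h))
  jvec <- if (L > 1L) unlist(lapply(model$J[-1], as.vector), use.names = FALSE) else numeric(0)
  header <- list(
    format_version = 1L,
    L = L, q = q,
    alphabet = model$alphabet$string,
    order = model$order$perm - 1L,
    order_label = model$order$label,
    h_length = length(hvec),
    J_length = length(jvec),
    meta = model$meta
  )
  hjson <- charToRaw(as.character(jsonlite::toJSON(
    header, auto_unbox = TRUE, digits = NA)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(ardca_magic(), con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  writeBin(hvec, con, size = 8L, endian = "little")
  writeBin(jvec, con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  if (!identical(magic, ardca_magic()))
    stop("not an ardca model file (bad magic): ", path)
  hlen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(hlen) != 1L || hlen <= 0L) stop("truncated header length")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)),
                               simplifyVector = TRUE)
  if (!identical(as.integer(header$format_version), 1L))
    stop("unsupported format_version: ", header$format_version)
  L <- as.integer(header$L); q <- as.integer(header$q)
  expected_h <- L * q
  expected_J <- as.integer(q * q * L * (L - 1) / 2)
  if (!identical(as.integer(header$h_length), expected_h))
    stop("field h_length inconsistent with L, q")
  if (!identical(as.integer(header$J_length), expected_J))
    stop("field J_length inconsistent with L, q")
  hvec <- readBin(con, "double", n = expected_h, size = 8L, endian = "little")
  if (length(hvec) != expected_h) stop("truncated array: h")
  jvec <- readBin(con, "double", n = expected_J, size = 8L, endian = "little")
  if (length(jvec) != expected_J) stop("truncated array: J")
  h <- matrix(hvec, L, q, byrow = TRUE)
  J <- vector("list", L)
  pos <- 0L
  for (i in seq_len(L)[-1]) {
    len <- q * q * (i - 1L)
    J[[i]] <- array(jvec[(pos + 1L):(pos + len)], dim = c(q, q, i - 1L))
    pos <- pos + len
  }
  meta <- header$meta
  if (is.null(meta)) meta <- list()
  new_ardca(
    h, J,
    order = new_site_order(as.integer(header$order) + 1L, header$order_label),
    alphabet = aa_alphabet(header$alphabet),
    meta = meta
  )
}
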