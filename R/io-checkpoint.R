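# Single-file checkpoint archive for transfer learning: a JSON header
# describing the architecture (layer kinds, sizes, order, parameter shapes)
# and metadata, followed by the named weight arrays as little-endian float64.
# Doubles round-trip bitwise. Format versioned via `format` in the header.

.ckpt_magic <- "AFKTCKPT1\n"

#' Bundle a model's architecture, weights and metadata
#'
#' @param architecture list of layer descriptors (fields `kind`, `config`,
#'   and `params`: named list of integer shape vectors).
#' @param weights named list of numeric arrays; every name must resolve to a
#'   `layer.param` entry of the architecture with a matching shape.
#' @param metadata named list (source dataset tag, epoch, seed, ...).
#' @return an object of class `checkpoint_bundle`.
#' @export
checkpoint_bundle <- function(architecture, weights, metadata = list()) {
  b <- structure(list(architecture = architecture, weights = weights,
                      metadata = metadata), class = "checkpoint_bundle")
  .ckpt_validate(b)
  b
}

.ckpt_shapes <- function(architecture) {
  shapes <- list()
  for (i in seq_along(architecture)) {
    layer <- architecture[[i]]
    for (p in names(layer$params))
      shapes[[sprintf("%s.%s", layer$name, p)]] <- as.integer(layer$params[[p]])
  }
  shapes
}

.ckpt_validate <- function(bundle) {
  shapes <- .ckpt_shapes(bundle$architecture)
  for (nm in names(bundle$weights)) {
    if (is.null(shapes[[nm]]))
      stopf("weight '%s' not resolvable against the architecture descriptor", nm)
    got <- dim(bundle$weights[[nm]])
    if (is.null(got)) got <- length(bundle$weights[[nm]])
    if (!identical(as.integer(got), shapes[[nm]]))
      stopf("shape mismatch for weight '%s': descriptor (%s) vs array (%s)",
            nm, paste(shapes[[nm]], collapse = "x"), paste(got, collapse = "x"))
  }
  missing <- setdiff(names(shapes), names(bundle$weights))
  if (length(missing))
    stopf("weights missing for: %s", paste(missing, collapse = ", "))
  invisible(bundle)
}

#' Save a checkpoint bundle to a single-file archive
#'
#' @param bundle a [checkpoint_bundle].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(bundle, path) {
  .ckpt_validate(bundle)
  arrays <- lapply(names(bundle$weights), function(nm) {
    w <- bundle$weights[[nm]]
    d <- dim(w); if (is.null(d)) d <- length(w)
    list(name = nm, dims = as.integer(d), length = length(w))
  })
  header <- jsonlite::toJSON(list(format = "affectkit-checkpoint-1",
                                  architecture = bundle$architecture,
                                  metadata = bundle$metadata,
                                  arrays = arrays),
                             auto_unbox = TRUE, digits = NA, null = "null")
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(.ckpt_magic, con, eos = NULL)
  writeBin(length(hraw), con, size = 4, endian = "little")
  writeBin(hraw, con)
  for (nm in names(bundle$weights))
    writeBin(as.double(bundle$weights[[nm]]), con, size = 8, endian = "little")
  invisible(path)
}

#' Load a checkpoint bundle from disk
#'
#' Verifies each stored array's shape against the architecture descriptor;
#' a tampered shape or an unresolvable weight name is an error.
#'
#' @param path checkpoint archive path.
#' @return a [checkpoint_bundle].
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(.ckpt_magic), useBytes = TRUE)
  if (!identical(magic, .ckpt_magic)) stopf("not an affectkit checkpoint: %s", path)
  hlen <- readBin(con, "integer", size = 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = FALSE)
  weights <- list()
  for (a in header$arrays) {
    v <- readBin(con, "double", n = a$length, size = 8, endian = "little")
    if (length(v) < a$length) stopf("truncated checkpoint array '%s'", a$name)
    dims <- unlist(a$dims)
    weights[[a$name]] <- if (length(dims) > 1) array(v, dims) else v
  }
  arch <- lapply(header$architecture, function(layer) {
    layer$params <- lapply(layer$params, function(s) as.integer(unlist(s)))
    layer
  })
  checkpoint_bundle(arch, weights, header$metadata)
}
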