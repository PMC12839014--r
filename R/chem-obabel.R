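# Internal wrappers around the obabel command line tool. All conversions are
# batched through temporary .smi files: one process call per compound set, with
# per-compound reject tracking (obabel silently drops unparseable entries, so
# identity is carried in the SMILES title column and missing titles are mapped
# back to rejects).

ob_available <- function() nzchar(Sys.which("obabel"))

.ob_check <- function() {
  if (!ob_available()) {
    stop("the 'obabel' executable was not found on PATH; OpenBabel >= 3 is required",
         call. = FALSE)
  }
}

# Run obabel on a set of SMILES. Returns the raw output lines of the requested
# format. `smiles` must not contain whitespace; titles are internal row tags.
.ob_run <- function(smiles, args, in_ext = ".smi") {
  .ob_check()
  tags <- paste0("x", seq_along(smiles))
  fin <- tempfile(fileext = in_ext)
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, tags), fin)
  # -e: skip unparseable entries instead of aborting the batch
  suppressWarnings(system2("obabel", c(fin, args, "-e", "-O", fout),
                           stdout = FALSE, stderr = FALSE))
  if (!file.exists(fout)) return(character(0))
  readLines(fout, warn = FALSE)
}

# Parse "<payload>\t<tag> [extra fields]" obabel smi-style output back into a
# matrix of fields aligned with the input; unmatched inputs give NA rows.
.ob_align <- function(lines, n, n_extra = 0L) {
  out <- matrix(NA_character_, nrow = n, ncol = 1L + n_extra)
  if (length(lines) == 0L) return(out)
  parts <- strsplit(trimws(lines), "[ \t]+")
  for (p in parts) {
    if (length(p) < 2L) next
    idx <- suppressWarnings(as.integer(sub("^x", "", p[2L])))
    if (is.na(idx) || idx < 1L || idx > n) next
    vals <- c(p[1L], if (n_extra > 0L) p[seq_len(n_extra) + 2L])
    out[idx, seq_along(vals)] <- vals
  }
  out
}

#' Canonical SMILES via OpenBabel
#'
#' Converts SMILES strings to OpenBabel canonical SMILES. Unparseable inputs
#' yield `NA` rather than an error, so callers can route them to a reject log.
#'
#' @param smiles character vector of SMILES strings (no whitespace).
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  bad <- is.na(smiles) | !nzchar(trimws(smiles)) | grepl("[[:space:]]", smiles)
  out <- rep(NA_character_, length(smiles))
  keep <- which(!bad)
  if (length(keep)) {
    lines <- .ob_run(smiles[keep], c("-ocan"))
    out[keep] <- .ob_align(lines, length(keep))[, 1L]
  }
  out
}

# Bulk physicochemical properties for parseable SMILES.
# Returns a data.frame aligned with the input (NA rows for rejects).
ob_properties <- function(smiles) {
  props <- c("MW", "logP", "TPSA", "HBD", "HBA1", "HBA2", "MR", "nF")
  n <- length(smiles)
  empty <- as.data.frame(matrix(NA_real_, n, length(props)))
  names(empty) <- props
  if (n == 0L) return(empty)
  lines <- .ob_run(smiles, c("-ocan", "--append", paste(props, collapse = " ")))
  m <- .ob_align(lines, n, n_extra = length(props))
  for (j in seq_along(props)) empty[[j]] <- as.numeric(m[, j + 1L])
  empty
}

# Molecular formula (e.g. "C7H8N2O") per SMILES; NA where unparseable.
ob_formula <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  lines <- .ob_run(smiles, c("-ocan", "--append", "formula MW"))
  m <- .ob_align(lines, n, n_extra = 2L)
  list(formula = m[, 2L], mw = as.numeric(m[, 3L]), cansmi = m[, 1L])
}

# Heavy-atom count from a molecular formula string (all atoms except H).
formula_heavy_atoms <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f)) return(NA_integer_)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    tot <- 0L
    for (tk in toks) {
      el <- gsub("[0-9]", "", tk)
      k <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", tk)))
      if (is.na(k)) k <- 1L
      if (el != "H") tot <- tot + k
    }
    tot
  }, integer(1), USE.NAMES = FALSE)
}

# Hex fingerprint block (FPS format) -> 0/1 integer matrix, one row per input.
.hex_to_bits <- function(hex, n_bits) {
  n <- length(hex)
  out <- matrix(0L, n, n_bits)
  ok <- which(!is.na(hex))
  if (!length(ok)) return(out)
  n_nib <- n_bits %/% 4L
  nib_tab <- matrix(0L, 16L, 4L)  # nibble value -> 4 bits, MSB first
  for (v in 0:15) nib_tab[v + 1L, ] <- as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L)
  chars <- matrix(NA_integer_, length(ok), n_nib)
  sp <- strsplit(tolower(hex[ok]), "")
  for (i in seq_along(ok)) {
    h <- strtoi(sp[[i]], 16L)
    if (length(h) == n_nib && !anyNA(h)) chars[i, ] <- h
  }
  for (j in seq_len(n_nib)) {
    cols <- (j - 1L) * 4L + 1:4
    v <- chars[, j]
    good <- !is.na(v)
    if (any(good)) out[ok[good], cols] <- nib_tab[v[good] + 1L, , drop = FALSE]
  }
  out
}

# Hashed fingerprints via obabel FPS output. type: "FP2" (1024-bit path
# fingerprint) or "ECFP4" (4096-bit circular, radius 2). Rows of NA-input or
# unparseable SMILES come back as all-zero with ok = FALSE.
ob_fingerprint <- function(smiles, type = c("FP2", "ECFP4", "ECFP0")) {
  type <- match.arg(type)
  n_bits <- if (type == "FP2") 1024L else 4096L
  n <- length(smiles)
  if (n == 0L) return(list(bits = matrix(0L, 0, n_bits), ok = logical(0)))
  lines <- .ob_run(smiles, c("-ofps", paste0("-xf", type)))
  lines <- lines[!startsWith(lines, "#")]
  # FPS payload lines are "<hex>\t<tag>"
  hex <- rep(NA_character_, n)
  parts <- strsplit(trimws(lines), "[ \t]+")
  for (p in parts) {
    if (length(p) < 2L) next
    idx <- suppressWarnings(as.integer(sub("^x", "", p[2L])))
    if (!is.na(idx) && idx >= 1L && idx <= n) hex[idx] <- p[1L]
  }
  list(bits = .hex_to_bits(hex, n_bits), ok = !is.na(hex))
}

# SMILES -> ChemmineR SDFset (via obabel 2D-less SDF). Unparseable entries are
# dropped; the returned `index` maps SDF entries back to input positions.
ob_sdfset <- function(smiles) {
  .ob_check()
  n <- length(smiles)
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, paste0("x", seq_len(n))), fin)
  suppressWarnings(system2("obabel", c(fin, "-osdf", "-e", "-O", fout),
                           stdout = FALSE, stderr = FALSE))
  if (!file.exists(fout) || file.size(fout) == 0)
    return(list(sdf = NULL, index = integer(0)))
  sdf <- suppressWarnings(ChemmineR::read.SDFset(fout))
  ids <- ChemmineR::sdfid(sdf)
  idx <- as.integer(sub("^x", "", ids))
  list(sdf = sdf, index = idx)
}
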