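# Chemical structure standardization. Applied identically to training, test,
# decoy and screening compounds: salt stripping to the parent fragment,
# ionization at physiological pH, canonicalization and generation of a
# deduplication key.

#' Strip a compound to its parent fragment
#'
#' Multi-fragment SMILES (salt forms, mixtures) are reduced to a single parent
#' fragment: the fragment with the greatest heavy-atom count, ties broken by
#' molecular weight, then by lexicographically smallest canonical SMILES.
#'
#' @param smiles character vector of SMILES strings.
#' @return data.frame with columns `parent_smiles` (canonical SMILES of the
#'   retained fragment, `NA` on failure), `n_fragments_removed`, and `reason`
#'   (`NA` for accepted rows, otherwise a reject reason code).
#' @examples
#' \dontrun{strip_to_parent(c("CC(=O)O.[Na+]", "c1ccccc1"))}
#' @export
strip_to_parent <- function(smiles) {
  n <- length(smiles)
  out <- data.frame(parent_smiles = rep(NA_character_, n),
                    n_fragments_removed = rep(NA_integer_, n),
                    reason = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  trimmed <- ifelse(is.na(smiles), "", trimws(smiles))
  empty <- !nzchar(trimmed)
  out$reason[empty] <- "missing_smiles"
  can <- rep(NA_character_, n)
  keep <- which(!empty)
  if (length(keep)) can[keep] <- canonical_smiles(trimmed[keep])
  bad <- which(!empty & is.na(can))
  out$reason[bad] <- "unparseable_smiles"

  ok <- which(!is.na(can))
  if (!length(ok)) return(out)

  frags <- strsplit(can[ok], ".", fixed = TRUE)
  nfr <- lengths(frags)
  single <- nfr == 1L
  out$parent_smiles[ok[single]] <- can[ok[single]]
  out$n_fragments_removed[ok[single]] <- 0L

  multi <- which(!single)
  if (length(multi)) {
    flat <- unlist(frags[multi])
    owner <- rep(seq_along(multi), nfr[multi])
    info <- ob_formula(flat)
    heavy <- formula_heavy_atoms(info$formula)
    heavy[is.na(heavy)] <- -1L
    mw <- info$mw
    mw[is.na(mw)] <- -1
    fsmi <- ifelse(is.na(info$cansmi), flat, info$cansmi)
    for (k in seq_along(multi)) {
      sel <- which(owner == k)
      # greatest heavy-atom count, then MW, then lexicographic smallest SMILES
      o <- order(-heavy[sel], -mw[sel], fsmi[sel])
      best <- sel[o[1L]]
      i <- ok[multi[k]]
      out$parent_smiles[i] <- fsmi[best]
      out$n_fragments_removed[i] <- length(sel) - 1L
    }
  }
  out
}

#' Ionize a structure at physiological pH
#'
#' Assigns pH 7.4 charge states with a fixed transformation rule table
#' (OpenBabel's pH model): carboxylic, sulfonic and phosphonic acids and
#' tetrazoles are deprotonated; aliphatic primary/secondary/tertiary amines,
#' amidines and guanidines are protonated; anilines, amides and aromatic
#' N-heterocycles stay neutral. The operation is idempotent.
#'
#' @param smiles character vector of single-fragment SMILES.
#' @return canonical SMILES with pH 7.4 charge states; `NA` on parse failure.
#' @examples
#' \dontrun{ionize_ph74("CC(=O)O")  # "CC(=O)[O-]"}
#' @export
ionize_ph74 <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  keep <- which(!is.na(smiles) & nzchar(trimws(smiles)))
  if (length(keep)) {
    lines <- .ob_run(trimws(smiles[keep]), c("-ocan", "-p7.4"))
    out[keep] <- .ob_align(lines, length(keep))[, 1L]
  }
  out
}

#' Standardization key for deduplication
#'
#' Canonical, ionization-normalized SMILES: two inputs describing the same
#' standardized structure (any atom ordering, neutral or pH-7.4 charge state)
#' map to the same key.
#'
#' @param parent_smiles character vector of single-fragment SMILES.
#' @return character vector of keys, `NA` on parse failure.
#' @export
make_std_key <- function(parent_smiles) {
  ionize_ph74(parent_smiles)
}

#' Standardize a compound table
#'
#' The full standardization pipeline: parent-fragment selection, pH 7.4
#' ionization and key generation, with an explicit reject log (no silent
#' drops).
#'
#' @param compounds data.frame with columns `compound_id` and `smiles`.
#' @return list with `std` (data.frame `compound_id`, `parent_smiles`,
#'   `std_key`, `n_fragments_removed`) and `rejects` (data.frame
#'   `compound_id`, `reason`).
#' @export
standardize_compounds <- function(compounds) {
  stopifnot(is.data.frame(compounds),
            all(c("compound_id", "smiles") %in% names(compounds)))
  if (anyDuplicated(compounds$compound_id))
    stop("compound_id values must be unique")
  par <- strip_to_parent(compounds$smiles)
  key <- rep(NA_character_, nrow(par))
  ok <- which(!is.na(par$parent_smiles))
  if (length(ok)) key[ok] <- make_std_key(par$parent_smiles[ok])
  # a parent that parses must ionize; treat failure as unparseable
  par$reason[ok][is.na(key[ok])] <- "unparseable_smiles"
  good <- !is.na(key) & is.na(par$reason)
  list(
    std = data.frame(compound_id = as.character(compounds$compound_id[good]),
                     parent_smiles = par$parent_smiles[good],
                     std_key = key[good],
                     n_fragments_removed = par$n_fragments_removed[good],
                     stringsAsFactors = FALSE),
    rejects = data.frame(compound_id = as.character(compounds$compound_id[!good]),
                         reason = par$reason[!good],
                         stringsAsFactors = FALSE)
  )
}

#' Read compounds from CSV, .smi or SDF
#'
#' @param path input file.
#' @param format `"csv"` (configurable column names), `"smi"`
#'   (whitespace-delimited SMILES + id) or `"sdf"`.
#' @param col_id,col_smiles column names for CSV input.
#' @return data.frame with columns `compound_id`, `smiles`.
#' @export
read_compounds <- function(path, format = c("csv", "smi", "sdf"),
                           col_id = "compound_id", col_smiles = "smiles") {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c(col_id, col_smiles) %in% names(df)))
      stop("CSV is missing column(s): ",
           paste(setdiff(c(col_id, col_smiles), names(df)), collapse = ", "))
    return(data.frame(compound_id = as.character(df[[col_id]]),
                      smiles = as.character(df[[col_smiles]]),
                      stringsAsFactors = FALSE))
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    smi <- vapply(parts, `[`, "", 1L)
    id <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, "")
    id[is.na(id)] <- paste0("cmpd", which(is.na(id)))
    return(data.frame(compound_id = id, smiles = smi, stringsAsFactors = FALSE))
  }
  .ob_check()
  fout <- tempfile(fileext = ".smi")
  on.exit(unlink(fout), add = TRUE)
  suppressWarnings(system2("obabel", c(path, "-ocan", "-O", fout),
                           stdout = FALSE, stderr = FALSE))
  if (!file.exists(fout)) stop("could not convert SDF: ", path)
  read_compounds(fout, "smi")
}

#' Write standardized compounds and the reject log
#'
#' @param std result of [standardize_compounds()].
#' @param path output CSV for standardized compounds.
#' @param reject_path optional output CSV for the reject log.
#' @return `path`, invisibly.
#' @export
write_standardized <- function(std, path, reject_path = NULL) {
  utils::write.csv(std$std, path, row.names = FALSE)
  if (!is.null(reject_path))
    utils::write.csv(std$rejects, reject_path, row.names = FALSE)
  invisible(path)
}
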