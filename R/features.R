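# The seven molecular representations: path fingerprint (1024), circular
# radius-2 fingerprint (1024, folded from 4096), substructure-key dictionary
# fingerprint (881), physicochemical descriptors (208, min-max scaled), and
# the three fingerprint+descriptor hybrids; plus the Tanimoto similarity.

#' Representation lengths
#' @return named integer vector of vector lengths per representation kind.
#' @export
feature_lengths <- function() {
  c(path_fp = 1024L, morgan_fp = 1024L, dict_fp = 881L, descriptors = 208L,
    hybridRR = 1232L, hybridMR = 1232L, hybridPR = 1089L)
}

.cs_set_kind <- function(m, kind) {
  attr(m, "kind") <- kind
  m
}

#' Feature kind of a matrix
#' @param x a feature matrix produced by the featurizers.
#' @return the kind string.
#' @export
feature_kind <- function(x) attr(x, "kind")

#' Path-based hashed fingerprint (1024 bits)
#'
#' Encodes linear atom-bond paths up to seven atoms, hashed onto a 1024-bit
#' vector (OpenBabel FP2). Invariant to the SMILES spelling of a molecule.
#'
#' @param smiles character vector of standardized SMILES.
#' @return integer 0/1 matrix, one row per compound, 1024 columns.
#' @export
path_fp <- function(smiles) {
  fp <- ob_fingerprint(smiles, "FP2")
  if (!all(fp$ok))
    stop("unparseable SMILES at position(s): ",
         paste(utils::head(which(!fp$ok), 5), collapse = ", "))
  .cs_set_kind(fp$bits, "path_fp")
}

#' Circular radius-2 hashed fingerprint (1024 bits)
#'
#' Extended-connectivity environments of each heavy atom up to two bonds
#' (OpenBabel ECFP4, radius 2), folded from 4096 to 1024 bits by OR-ing
#' 1024-bit blocks.
#'
#' @inheritParams path_fp
#' @return integer 0/1 matrix, 1024 columns.
#' @export
morgan_fp <- function(smiles) {
  fp <- ob_fingerprint(smiles, "ECFP4")
  if (!all(fp$ok))
    stop("unparseable SMILES at position(s): ",
         paste(utils::head(which(!fp$ok), 5), collapse = ", "))
  b <- fp$bits
  folded <- (b[, 1:1024, drop = FALSE] | b[, 1025:2048, drop = FALSE] |
               b[, 2049:3072, drop = FALSE] | b[, 3073:4096, drop = FALSE])
  .cs_set_kind(matrix(as.integer(folded), nrow = nrow(b)), "morgan_fp")
}

#' Substructure-key dictionary fingerprint (881 bits)
#'
#' Presence/absence of the 881 structural keys of the shipped, versioned
#' dictionary (see [dict_keys()]).
#'
#' @inheritParams path_fp
#' @return integer 0/1 matrix, 881 columns.
#' @export
dict_fp <- function(smiles) {
  keys <- dict_keys()
  graphs <- mol_graph_batch(smiles)
  out <- matrix(0L, length(smiles), nrow(keys))
  for (i in seq_along(graphs)) {
    st <- .cs_mol_stats(graphs[[i]])
    out[i, ] <- .cs_dict_eval(graphs[[i]], st, keys)
  }
  colnames(out) <- keys$name
  .cs_set_kind(out, "dict_fp")
}

# per-element property tables for autocorrelation descriptors
.cs_el_Z <- c(C = 6, N = 7, O = 8, S = 16, P = 15, F = 9, Cl = 17, Br = 35,
              I = 53, B = 5)
.cs_el_EN <- c(C = 2.55, N = 3.04, O = 3.44, S = 2.58, P = 2.19, F = 3.98,
               Cl = 3.16, Br = 2.96, I = 2.66, B = 2.04)
.cs_el_RC <- c(C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07, F = 0.57,
               Cl = 1.02, Br = 1.20, I = 1.39, B = 0.84)
.cs_el_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
                 F = 18.998, Cl = 35.45, Br = 79.904, I = 126.9, B = 10.81)

.cs_prop_of <- function(el, tab, default) {
  x <- tab[el]
  x[is.na(x)] <- default
  unname(x)
}

# Moreau-Broto and Moran autocorrelations of an atomic property over
# topological lags
.cs_autocorr <- function(D, w, lags) {
  ats <- numeric(length(lags)); mor <- numeric(length(lags))
  n <- length(w)
  wc <- w - mean(w)
  s2 <- mean(wc^2)
  for (k in seq_along(lags)) {
    idx <- which(D == lags[k], arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    if (nrow(idx) == 0) next
    ats[k] <- sum(w[idx[, 1]] * w[idx[, 2]])
    if (s2 > 0)
      mor[k] <- mean(wc[idx[, 1]] * wc[idx[, 2]]) / s2
  }
  list(ats = ats, moran = mor)
}

# one molecule -> the 200 graph-derived descriptor values
.cs_graph_descriptors <- function(gr, st) {
  el <- gr$el; deg <- gr$deg; D <- gr$dist
  n <- length(el); m <- nrow(gr$bonds)
  z <- function(x) ifelse(is.finite(x), x, 0)
  out <- c()
  nm <- function(v, names) { names(v) <- names; out <<- c(out, v) }
  nm(as.numeric(st$elc), paste0("n", names(st$elc)))
  n_het <- sum(!(el %in% "C")); n_hal <- sum(el %in% .cs_halogens)
  nm(c(n, n_het, n_hal, z(n_het / n), z(n_hal / n), gr$n_arom,
       z(gr$n_arom / n), gr$n_pos, gr$n_neg),
     c("n_heavy", "n_hetero", "n_halogen", "frac_hetero", "frac_halogen",
       "n_arom", "frac_arom", "n_pos", "n_neg"))
  ord <- gr$bonds[, 3]
  nm(c(m, sum(ord == 1), sum(ord == 2), sum(ord == 3),
       z(sum(ord > 1) / m), z(mean(ord))),
     c("n_bonds", "n_single", "n_double", "n_triple", "frac_multi",
       "mean_bond_order"))
  nm(c(tabulate(pmin(deg, 4L), 4L), z(tabulate(pmin(deg, 4L), 4L) / n),
       mean(deg), max(deg), z(stats::var(deg))),
     c(paste0("n_deg", 1:4), paste0("frac_deg", 1:4),
       c("mean_deg", "max_deg", "var_deg")))
  rs <- gr$ring_sizes
  nm(c(gr$n_rings, if (length(rs)) min(rs) else 0,
       if (length(rs)) max(rs) else 0, if (length(rs)) mean(rs) else 0,
       vapply(3:9, function(s) sum(rs == s), 0)),
     c("n_rings", "min_ring", "max_ring", "mean_ring", paste0("n_ring", 3:9)))
  Df <- D[upper.tri(D)]
  Df <- Df[is.finite(Df)]
  ecc <- apply(ifelse(is.finite(D), D, 0), 1, max)
  nm(c(sum(Df), z(mean(Df)), max(c(ecc, 0)), if (n > 1) min(ecc) else 0,
       mean(ecc), sum(1 / Df[Df > 0])),
     c("wiener", "mean_dist", "diameter", "radius", "mean_ecc", "harary"))
  du <- deg[gr$bonds[, 1]]; dv <- deg[gr$bonds[, 2]]
  nm(c(sum(deg^2), sum(du * dv), z(sum(1 / sqrt(du * dv))),
       sum(du + dv - 2), z(2 * m / (n * (n - 1))), sum(deg >= 3)),
     c("zagreb1", "zagreb2", "randic", "platt", "density", "n_branch"))
  A <- matrix(0, n, n)
  if (nrow(gr$bonds) > 0) {
    A[gr$bonds[, 1:2, drop = FALSE]] <- 1
    A <- pmax(A, t(A))
  }
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  L <- diag(deg, nrow = n) - A
  evl <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  nm(c(max(ev), sum(abs(ev)), vapply(2:6, function(k) sum(ev^k) / n, 0),
       if (n > 1) sort(evl)[2] else 0, max(evl)),
     c("adj_lmax", "energy", paste0("spec_m", 2:6), "lap_alg_conn", "lap_lmax"))
  props <- list(Z = .cs_prop_of(el, .cs_el_Z, 6),
                EN = .cs_prop_of(el, .cs_el_EN, 2.5),
                deg = deg,
                het = as.numeric(!(el %in% "C")),
                rc = .cs_prop_of(el, .cs_el_RC, 1.0))
  for (p in names(props)) {
    ac <- .cs_autocorr(D, props[[p]], 1:8)
    nm(ac$ats, paste0("ats_", p, 1:8))
    nm(ac$moran, paste0("moran_", p, 1:8))
  }
  dc <- vapply(1:15, function(d) sum(Df == d), 0)
  nm(z(dc / max(length(Df), 1)), paste0("fdist", 1:15))
  for (e in c("C", "N", "O", "S", "P"))
    nm(z(mean(deg[el == e])), paste0("mean_deg_", e))
  bp <- c("C-C:1", "C-C:2", "C-N:1", "C-N:2", "C-N:3", "C-O:1", "C-O:2",
          "C-S:1", "C-Cl:1", "C-F:1")
  cntb <- as.integer(st$bond_tab[bp]); cntb[is.na(cntb)] <- 0L
  nm(as.numeric(cntb), paste0("b_", gsub(":", ".", bp)))
  tp <- c("C-C-C", "C-C-N", "C-C-O", "N-C-O", "O-C-O", "C-N-C", "C-O-C",
          "C-S-C", "O-S-O", "N-C-N")
  cntt <- as.integer(st$tri_tab[tp]); cntt[is.na(cntt)] <- 0L
  nm(as.numeric(cntt), paste0("t_", tp))
  p2 <- sum(choose(deg, 2))
  p3 <- sum(Df == 3)
  term <- sum(deg == 1)
  flex <- sum(ord == 1 & du > 1 & dv > 1)
  mass <- .cs_prop_of(el, .cs_el_MASS, 12)
  nm(c(p2, p3, z(n * (n - 1)^2 / p2^2), flex, term, mean(mass)),
     c("path2_count", "path3_pairs", "kappa1", "n_rotatable_like",
       "n_terminal", "mean_atomic_mass"))
  nm(c(z(gr$n_rings / n), z(n_het / sum(el == "C")), z(sum(el == "O") / sum(el == "C")),
       z(sum(el == "N") / sum(el == "C")), z(n_hal / sum(el == "C")),
       z(sum(mass) / n)),
     c("rings_per_atom", "hetero_per_C", "O_per_C", "N_per_C",
       "halogen_per_C", "mass_per_heavy"))
  out
}

#' Physicochemical descriptors (208 attributes)
#'
#' A fixed, versioned manifest of 208 numerical descriptors per compound:
#' 8 bulk physicochemical properties (molecular weight, logP, topological
#' polar surface area, H-bond donor/acceptor counts, molar refractivity,
#' fluorine count) plus 200 graph and topology derived attributes (element,
#' bond, degree and ring counts; distance-based indices; spectral
#' descriptors; Moreau-Broto and Moran autocorrelations; shape indices).
#' Raw values; scale with [fit_minmax()] / [apply_minmax()].
#'
#' @inheritParams path_fp
#' @return numeric matrix, 208 named columns.
#' @export
calc_descriptors <- function(smiles) {
  graphs <- mol_graph_batch(smiles)
  props <- ob_properties(smiles)
  rows <- vector("list", length(smiles))
  for (i in seq_along(graphs)) {
    st <- .cs_mol_stats(graphs[[i]])
    rows[[i]] <- c(unlist(props[i, ]), .cs_graph_descriptors(graphs[[i]], st))
  }
  out <- do.call(rbind, rows)
  if (ncol(out) != 208L)
    stop("descriptor manifest drifted: expected 208, got ", ncol(out))
  .cs_set_kind(out, "descriptors")
}

#' The descriptor manifest
#' @return character vector of the 208 descriptor names, in order.
#' @export
descriptor_manifest <- function() {
  colnames(calc_descriptors("c1ccccc1C(=O)[O-]"))
}

#' Fit a per-feature min-max scaler on the training split
#'
#' @param X training descriptor matrix.
#' @return a `cs_scaler` with per-feature minimum, maximum and median (the
#'   median replaces non-finite values at transform time).
#' @export
fit_minmax <- function(X) {
  med <- apply(X, 2, function(v) stats::median(v[is.finite(v)]))
  med[!is.finite(med)] <- 0
  Xf <- X
  for (j in seq_len(ncol(X))) Xf[!is.finite(Xf[, j]), j] <- med[j]
  structure(list(min = apply(Xf, 2, min), max = apply(Xf, 2, max),
                 median = med), class = "cs_scaler")
}

#' Apply (or invert) a fitted min-max scaler
#'
#' Transforms features to `[0, 1]` by the training-split range; values outside
#' the training range are clipped, constant training features map to 0, and
#' non-finite values are replaced by the training median (logged via a
#' "cs_nonfinite" condition).
#'
#' @param scaler a [fit_minmax()] result.
#' @param X descriptor matrix.
#' @return scaled matrix with the same dimensions.
#' @export
apply_minmax <- function(scaler, X) {
  stopifnot(inherits(scaler, "cs_scaler"), ncol(X) == length(scaler$min))
  n_bad <- sum(!is.finite(X))
  if (n_bad > 0) {
    for (j in seq_len(ncol(X)))
      X[!is.finite(X[, j]), j] <- scaler$median[j]
    message(n_bad, " non-finite descriptor value(s) replaced by training median")
  }
  rng <- scaler$max - scaler$min
  out <- sweep(X, 2, scaler$min)
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  .cs_set_kind(out, "descriptors")
}

#' @rdname apply_minmax
#' @param Xs a scaled matrix with values in the training range.
#' @export
invert_minmax <- function(scaler, Xs) {
  stopifnot(inherits(scaler, "cs_scaler"))
  rng <- scaler$max - scaler$min
  sweep(sweep(Xs, 2, rng, "*"), 2, scaler$min, "+")
}

#' Concatenate a fingerprint with scaled descriptors into a hybrid
#'
#' Fingerprint first, descriptors second. The hybrid kind follows the
#' fingerprint: path -> hybridRR (1232), circular -> hybridMR (1232),
#' dictionary -> hybridPR (1089).
#'
#' @param fp fingerprint matrix from [path_fp()], [morgan_fp()] or [dict_fp()].
#' @param desc scaled descriptor matrix from [apply_minmax()].
#' @return numeric hybrid matrix.
#' @export
hybrid_features <- function(fp, desc) {
  map <- c(path_fp = "hybridRR", morgan_fp = "hybridMR", dict_fp = "hybridPR")
  fk <- feature_kind(fp)
  if (is.null(fk) || !fk %in% names(map))
    stop("hybrid base must be a fingerprint matrix, got kind: ",
         if (is.null(fk)) "<none>" else fk)
  if (!identical(feature_kind(desc), "descriptors"))
    stop("second argument must be a (scaled) descriptor matrix")
  if (nrow(fp) != nrow(desc)) stop("row mismatch between fingerprint and descriptors")
  .cs_set_kind(cbind(fp, desc), unname(map[fk]))
}

#' Tanimoto similarity between two binary fingerprints
#'
#' `T = s / (a + b - s)` where `s` is the number of shared on-bits and `a`,
#' `b` the on-bit counts of each fingerprint; defined as 0 when both
#' fingerprints are empty.
#'
#' @param x,y binary 0/1 vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(x, y) {
  if (length(x) != length(y)) stop("fingerprint length mismatch")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("tanimoto() requires binary fingerprints; use tanimoto_kernel_matrix() for continuous vectors")
  s <- sum(x == 1 & y == 1)
  den <- sum(x) + sum(y) - s
  if (den == 0) return(0)
  s / den
}
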