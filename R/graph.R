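# Molecular graphs and per-molecule structural statistics, extracted once per
# compound batch and shared by the substructure-key fingerprint and the
# descriptor calculator.

.cs_atom_token_re <- "\\[[^]]+\\]|Cl|Br|[BCNOSPFIbcnosp*]"

# SMILES-level token statistics (aromatic atoms, formal charges). Assumes the
# canonical SMILES the standardizer emits.
.cs_smiles_stats <- function(smi) {
  toks <- regmatches(smi, gregexpr(.cs_atom_token_re, smi))[[1]]
  arom <- grepl("^(\\[[a-z])|^[bcnosp]$", toks)
  pos <- grepl("\\+", toks)
  neg <- grepl("-", toks) & grepl("^\\[", toks)
  list(n_arom = sum(arom), n_pos = sum(pos), n_neg = sum(neg))
}

# Batch SMILES -> list of molecular graphs. Each graph holds the element
# vector, bond matrix (atom1, atom2, order), degrees, topological distance
# matrix and ring information. Errors if any input fails to parse (featurizer
# precondition: standardized SMILES).
mol_graph_batch <- function(smiles) {
  n <- length(smiles)
  res <- ob_sdfset(smiles)
  if (length(res$index) != n || is.null(res$sdf))
    stop("featurizer input contains unparseable SMILES at position(s): ",
         paste(utils::head(setdiff(seq_len(n), res$index), 5), collapse = ", "))
  ab <- ChemmineR::atomblock(res$sdf)
  bb <- ChemmineR::bondblock(res$sdf)
  valid <- suppressWarnings(ChemmineR::validSDF(res$sdf))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    i <- res$index[k]
    if (!valid[k]) {
      # bond-free molecule (e.g. a single heavy atom): SDF bond block is
      # absent and ChemmineR returns placeholders; recover atoms from tokens
      toks <- regmatches(smiles[i], gregexpr(.cs_atom_token_re, smiles[i]))[[1]]
      el <- vapply(toks, function(tk) {
        e <- sub("^\\[([A-Za-z][a-z]?).*$", "\\1", tk)
        e <- sub("^([A-Za-z][a-z]?).*$", "\\1", e)
        paste0(toupper(substr(e, 1, 1)), substring(e, 2))
      }, "", USE.NAMES = FALSE)
      bonds <- matrix(integer(0), ncol = 3)
    } else {
      el <- sub("_.*$", "", rownames(ab[[k]]))
      bonds <- bb[[k]]
      if (is.null(dim(bonds)) && length(bonds) >= 3) bonds <- matrix(bonds, nrow = 1)
      if (is.null(dim(bonds)) || nrow(bonds) == 0 || ncol(bonds) < 3) {
        bonds <- matrix(integer(0), ncol = 3)
      } else {
        bonds <- matrix(as.integer(bonds[, 1:3]), ncol = 3)
      }
    }
    na <- length(el)
    deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = na)
    g <- igraph::make_empty_graph(n = na, directed = FALSE)
    if (nrow(bonds) > 0)
      g <- igraph::add_edges(g, t(bonds[, 1:2, drop = FALSE]))
    D <- igraph::distances(g)
    # smallest cycle through each non-tree edge (ring-size profile)
    ring_sizes <- integer(0)
    n_comp <- igraph::components(g)$no
    n_cyc <- nrow(bonds) - na + n_comp
    if (n_cyc > 0) {
      tr <- igraph::mst(g)
      in_tree <- !is.na(igraph::get_edge_ids(
        tr, t(bonds[, 1:2, drop = FALSE]), error = FALSE)) &
        igraph::get_edge_ids(tr, t(bonds[, 1:2, drop = FALSE]), error = FALSE) > 0
      for (e in which(!in_tree)) {
        g2 <- igraph::delete_edges(
          g, igraph::get_edge_ids(g, bonds[e, 1:2]))
        d <- igraph::distances(g2, v = bonds[e, 1], to = bonds[e, 2])[1, 1]
        if (is.finite(d)) ring_sizes <- c(ring_sizes, d + 1L)
      }
    }
    sm <- .cs_smiles_stats(smiles[i])
    out[[i]] <- list(el = el, bonds = bonds, deg = deg, dist = D,
                     n_rings = max(n_cyc, 0L), ring_sizes = ring_sizes,
                     n_arom = sm$n_arom, n_pos = sm$n_pos, n_neg = sm$n_neg)
  }
  out
}

.cs_halogens <- c("F", "Cl", "Br", "I")
.cs_dict_elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")

# element -> coarse class used by path-2 and distance keys
.cs_el_class <- function(el) {
  cls <- rep("Z", length(el))
  cls[el == "C"] <- "C"; cls[el == "N"] <- "N"; cls[el == "O"] <- "O"
  cls[el == "S"] <- "S"; cls[el %in% .cs_halogens] <- "X"
  cls
}

# Precompute the count tables a molecule's dictionary keys and descriptors are
# evaluated from.
.cs_mol_stats <- function(gr) {
  el <- gr$el
  elc <- table(factor(el, levels = .cs_dict_elements))
  cls <- .cs_el_class(el)
  # bond pair/order counts, unordered element pair
  p1 <- el[gr$bonds[, 1]]; p2 <- el[gr$bonds[, 2]]
  lo <- pmin(p1, p2); hi <- pmax(p1, p2)
  bond_keys <- paste0(lo, "-", hi, ":", gr$bonds[, 3])
  bond_tab <- table(bond_keys)
  # path-2 class triples centred on each atom
  tri <- character(0)
  nb <- vector("list", length(el))
  for (b in seq_len(nrow(gr$bonds))) {
    nb[[gr$bonds[b, 1]]] <- c(nb[[gr$bonds[b, 1]]], gr$bonds[b, 2])
    nb[[gr$bonds[b, 2]]] <- c(nb[[gr$bonds[b, 2]]], gr$bonds[b, 1])
  }
  for (a in seq_along(el)) {
    nbs <- nb[[a]]
    if (length(nbs) < 2) next
    cmb <- utils::combn(cls[nbs], 2)
    tri <- c(tri, paste0(pmin(cmb[1, ], cmb[2, ]), "-", cls[a], "-",
                         pmax(cmb[1, ], cmb[2, ])))
  }
  tri_tab <- table(tri)
  # heteroatom class pairs by topological distance
  het <- which(cls %in% c("N", "O", "S", "X"))
  dist_keys <- character(0)
  if (length(het) >= 2) {
    cm <- utils::combn(het, 2)
    d <- gr$dist[cbind(cm[1, ], cm[2, ])]
    ok <- is.finite(d) & d >= 2 & d <= 6
    dist_keys <- paste0(pmin(cls[cm[1, ok]], cls[cm[2, ok]]), "-",
                        pmax(cls[cm[1, ok]], cls[cm[2, ok]]), ":", d[ok])
  }
  list(elc = elc, bond_tab = bond_tab, tri_tab = tri_tab,
       dist_tab = table(dist_keys), nb = nb, cls = cls)
}
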