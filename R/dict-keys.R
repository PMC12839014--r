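# The 881-entry substructure-key dictionary (version "cs-dict-1"). The key
# family is generated in a fixed order from graph-derived structural
# predicates — element-count thresholds, ring keys, degree/charge
# environments, bonded element-pair keys, path-2 class triples and
# heteroatom topological-distance keys — and truncated to exactly 881 keys.
# The order is part of the dictionary version and must never change silently.

.cs_dict_cache <- new.env(parent = emptyenv())

#' The substructure-key dictionary
#'
#' @return data.frame with columns `index`, `name`, `kind`, `a`, `b`, `t`
#'   describing each of the 881 keys, in their fixed, versioned order.
#' @export
dict_keys <- function() {
  if (!is.null(.cs_dict_cache$keys)) return(.cs_dict_cache$keys)
  rows <- list()
  add <- function(kind, a = "", b = "", t = 0L, name) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, kind = kind, a = a, b = b, t = as.integer(t),
      stringsAsFactors = FALSE)
  }
  # A: element-count thresholds
  for (el in .cs_dict_elements)
    for (t in 1:8) add("elcount", el, t = t, name = sprintf("n%s>=%d", el, t))
  # A2: totals
  for (t in seq(5, 50, by = 5)) add("heavy", t = t, name = sprintf("heavy>=%d", t))
  for (t in 1:10) add("hetero", t = t, name = sprintf("hetero>=%d", t))
  for (t in 1:5) add("halogen", t = t, name = sprintf("halogen>=%d", t))
  # B: ring keys
  for (t in 1:8) add("nrings", t = t, name = sprintf("rings>=%d", t))
  for (t in c(3, 4, 5, 6, 8, 10, 12, 14, 16, 18))
    add("narom", t = t, name = sprintf("arom>=%d", t))
  for (s in 3:9) add("ringsize", a = s, t = 1L, name = sprintf("ring%d", s))
  for (s in c(5, 6)) for (t in 2:3)
    add("ringsize", a = s, t = t, name = sprintf("ring%d>=%d", s, t))
  # C: element-degree environments and formal charges
  for (el in c("C", "N", "O", "S", "P")) for (d in 1:4) {
    add("degree", el, d, 1L, name = sprintf("%s.deg%d", el, d))
  }
  for (el in c("C", "N", "O", "S", "P")) for (d in 1:4) {
    add("degree", el, d, 2L, name = sprintf("%s.deg%d>=2", el, d))
  }
  for (t in 1:2) add("poscharge", t = t, name = sprintf("pos>=%d", t))
  for (t in 1:2) add("negcharge", t = t, name = sprintf("neg>=%d", t))
  # D: bonded element pairs by bond order
  els <- .cs_dict_elements
  pairs <- list()
  for (i in seq_along(els)) for (j in i:length(els))
    pairs[[length(pairs) + 1L]] <- c(els[i], els[j])
  for (ord in 1:3) for (p in pairs)
    add("bond", paste0(p[1], "-", p[2]), ord, 1L,
        name = sprintf("%s-%s:%d", p[1], p[2], ord))
  for (ord in 1:3) for (p in pairs)
    add("bond", paste0(p[1], "-", p[2]), ord, 2L,
        name = sprintf("%s-%s:%d>=2", p[1], p[2], ord))
  for (ord in 1:2) for (p in pairs)
    add("bond", paste0(p[1], "-", p[2]), ord, 3L,
        name = sprintf("%s-%s:%d>=3", p[1], p[2], ord))
  # E: path-2 class triples
  cl <- c("C", "N", "O", "S", "X", "Z")
  for (t in 1:2) for (m in cl)
    for (i in seq_along(cl)) for (j in i:length(cl))
      add("path2", paste0(cl[i], "-", m, "-", cl[j]), t = t,
          name = sprintf("%s-%s-%s%s", cl[i], m, cl[j],
                         if (t > 1) ">=2" else ""))
  # F: heteroatom class pairs at topological distance
  hcl <- c("N", "O", "S", "X")
  for (d in 3:4) for (i in seq_along(hcl)) for (j in i:length(hcl))
    add("hetdist", paste0(hcl[i], "-", hcl[j]), d, 1L,
        name = sprintf("%s-%s@%d", hcl[i], hcl[j], d))
  keys <- do.call(rbind, rows)
  keys <- keys[seq_len(881L), , drop = FALSE]  # fixed truncation, cs-dict-1
  keys$index <- seq_len(nrow(keys))
  .cs_dict_cache$keys <- keys
  keys
}

# evaluate all 881 keys for one molecule's stats (vectorized per key kind)
.cs_dict_eval <- function(gr, st, keys) {
  v <- integer(nrow(keys))
  look <- function(tab, nm) {
    x <- as.integer(tab[nm])
    x[is.na(x)] <- 0L
    x
  }
  scalar_ge <- function(kind, value) {
    idx <- keys$kind == kind
    v[idx] <<- as.integer(value >= keys$t[idx])
  }
  idx <- keys$kind == "elcount"
  v[idx] <- as.integer(as.integer(st$elc[keys$a[idx]]) >= keys$t[idx])
  scalar_ge("heavy", length(gr$el))
  scalar_ge("hetero", sum(!(gr$el %in% c("C", "H"))))
  scalar_ge("halogen", sum(gr$el %in% .cs_halogens))
  scalar_ge("nrings", gr$n_rings)
  scalar_ge("narom", gr$n_arom)
  scalar_ge("poscharge", gr$n_pos)
  scalar_ge("negcharge", gr$n_neg)
  rs_tab <- table(gr$ring_sizes)
  idx <- keys$kind == "ringsize"
  v[idx] <- as.integer(look(rs_tab, keys$a[idx]) >= keys$t[idx])
  degtab <- table(paste0(gr$el, ".", pmin(gr$deg, 8L)))
  idx <- keys$kind == "degree"
  v[idx] <- as.integer(look(degtab, paste0(keys$a[idx], ".", keys$b[idx])) >=
                         keys$t[idx])
  idx <- keys$kind == "bond"
  v[idx] <- as.integer(look(st$bond_tab, paste0(keys$a[idx], ":", keys$b[idx])) >=
                         keys$t[idx])
  idx <- keys$kind == "path2"
  v[idx] <- as.integer(look(st$tri_tab, keys$a[idx]) >= keys$t[idx])
  idx <- keys$kind == "hetdist"
  v[idx] <- as.integer(look(st$dist_tab, paste0(keys$a[idx], ":", keys$b[idx])) >=
                         keys$t[idx])
  v
}
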