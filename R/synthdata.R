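# Synthetic ChEMBL-like data: activity tables, decoy libraries and screening
# libraries built from a scaffold-decoration grammar with a planted
# substructure -> potency signal. The grammar (rather than random graph
# sampling) keeps pharmacophore presence controllable and substructure
# checkable, which is what the downstream signal-recovery checks need.

# run code under a local, restorable RNG state
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  expr
}

# two-slot scaffold templates; both slots are always filled
.cs_scaffolds <- c(
  "c1ccc(%s)cc1-c1ccc(%s)cc1",            # biphenyl
  "c1ccc(%s)cc1Cc1ccc(%s)cc1",            # diphenylmethane
  "c1ccc(%s)cc1CCc1ccc(%s)cc1",           # bibenzyl
  "c1ccc(%s)cc1Oc1ccc(%s)cc1",            # diphenyl ether
  "c1ccc(%s)cc1NC(=O)c1ccc(%s)cc1",       # benzanilide
  "c1ccc(%s)cc1S(=O)(=O)c1ccc(%s)cc1",    # diphenyl sulfone
  "c1ccc(%s)cc1-c1ccc(%s)nc1",            # phenylpyridine
  "c1ccc(%s)cc1C(=O)Nc1ccc(%s)nc1"        # pyridyl benzamide
)

# plain substituents (branch-attached); none contains a pharmacophore
.cs_substituents <- c(
  "C", "CC", "CCC", "C(C)C", "OC", "OCC", "F", "Cl", "Br",
  "C#N", "C(=O)OC", "C(=O)N", "N(C)C", "CCN", "O", "CO",
  "S(C)(=O)=O", "C(F)(F)F"
)

.cs_linkers <- c("", "C", "CC", "OC")

# planted pharmacophore fragments (K = 4), branch-attached; their SMILES
# double as SMARTS for substructure checks
.cs_pharmacophores <- c(
  morpholinosulfonyl  = "S(=O)(=O)N1CCOCC1",
  benzothiazole_amide = "C(=O)Nc1nc2ccccc2s1",
  tetrazole           = "c1nnn[nH]1",
  indole_carboxamide  = "NC(=O)c1cc2cc(ccc2[nH]1)C"
)

#' Pharmacophore fragments planted by the synthetic-data generator
#'
#' @return named character vector of fragment SMILES (usable as SMARTS).
#' @export
pharmacophore_fragments <- function() .cs_pharmacophores

#' Configuration for the synthetic activity-data generator
#'
#' @param n_compounds number of distinct compounds.
#' @param seed integer seed; all generator output is a deterministic function
#'   of the configuration and this seed.
#' @param frac_ic50 fraction of records reported as IC50 (the remainder is
#'   split evenly over EC50, Ki, Kd).
#' @param frac_gt_relation fraction of records emitted as censored ">" rows.
#' @param frac_salted fraction of rows emitted as salt forms.
#' @param frac_duplicates fraction of compounds emitted twice with a second
#'   activity type.
#' @param frac_pharmacophore fraction of compounds carrying a planted
#'   pharmacophore fragment.
#' @param mu_active,mu_inactive mean pActivity of pharmacophore-bearing and
#'   plain compounds.
#' @param sigma pActivity standard deviation (> 0).
#' @param censor_value_nM concentration (nM) reported on censored ">" rows.
#' @return a `cs_synth_config` list.
#' @export
synth_config <- function(n_compounds = 2000L, seed = 1L,
                         frac_ic50 = 0.8, frac_gt_relation = 0.10,
                         frac_salted = 0.15, frac_duplicates = 0.10,
                         frac_pharmacophore = 0.7,
                         mu_active = 7.8, mu_inactive = 4.5, sigma = 0.6,
                         censor_value_nM = 10000) {
  fr <- c(frac_ic50, frac_gt_relation, frac_salted, frac_duplicates,
          frac_pharmacophore)
  stopifnot(n_compounds >= 1, all(fr >= 0 & fr <= 1), sigma > 0,
            mu_active > mu_inactive, censor_value_nM > 0)
  structure(list(n_compounds = as.integer(n_compounds), seed = as.integer(seed),
                 frac_ic50 = frac_ic50, frac_gt_relation = frac_gt_relation,
                 frac_salted = frac_salted, frac_duplicates = frac_duplicates,
                 frac_pharmacophore = frac_pharmacophore,
                 mu_active = mu_active, mu_inactive = mu_inactive,
                 sigma = sigma, censor_value_nM = censor_value_nM),
            class = "cs_synth_config")
}

# assemble one batch of candidate molecules from the grammar
.cs_assemble <- function(k, frac_pharm) {
  sc <- sample(.cs_scaffolds, k, replace = TRUE)
  pharm <- stats::runif(k) < frac_pharm
  r1 <- character(k)
  link1 <- sample(.cs_linkers, k, replace = TRUE)
  r1[pharm] <- paste0(link1[pharm],
                      sample(.cs_pharmacophores, sum(pharm), replace = TRUE))
  r1[!pharm] <- paste0(link1[!pharm],
                       sample(.cs_substituents, sum(!pharm), replace = TRUE))
  r2 <- paste0(sample(.cs_linkers, k, replace = TRUE),
               sample(.cs_substituents, k, replace = TRUE))
  data.frame(smiles = sprintf(sc, r1, r2), has_pharmacophore = pharm,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic compound library
#'
#' Builds `n_compounds` distinct, parseable molecules by combining ring
#' scaffolds, linkers and substituents from a fixed grammar. A configurable
#' fraction carries one of the planted pharmacophore fragments, and each
#' compound gets a true pActivity drawn from the pharmacophore-dependent
#' normal distribution. Fully reproducible from the seed.
#'
#' @param cfg a [synth_config()].
#' @return data.frame with `compound_id`, `smiles`, `has_pharmacophore`,
#'   `true_pActivity`.
#' @export
generate_library <- function(cfg) {
  stopifnot(inherits(cfg, "cs_synth_config"))
  .with_seed(cfg$seed, {
    got <- data.frame(smiles = character(0), has_pharmacophore = logical(0),
                      key = character(0), stringsAsFactors = FALSE)
    tries <- 0L
    while (nrow(got) < cfg$n_compounds && tries < 60L) {
      tries <- tries + 1L
      k <- max(64L, ceiling((cfg$n_compounds - nrow(got)) * 1.4))
      cand <- .cs_assemble(k, cfg$frac_pharmacophore)
      cand$key <- make_std_key(cand$smiles)
      cand <- cand[!is.na(cand$key) & !duplicated(cand$key) &
                     !(cand$key %in% got$key), , drop = FALSE]
      got <- rbind(got, cand)
    }
    if (nrow(got) < cfg$n_compounds)
      stop("grammar space exhausted before reaching ", cfg$n_compounds,
           " distinct compounds")
    got <- got[seq_len(cfg$n_compounds), , drop = FALSE]
    mu <- ifelse(got$has_pharmacophore, cfg$mu_active, cfg$mu_inactive)
    data.frame(compound_id = sprintf("SYN%05d", seq_len(cfg$n_compounds)),
               smiles = got$smiles,
               has_pharmacophore = got$has_pharmacophore,
               true_pActivity = stats::rnorm(cfg$n_compounds, mu, cfg$sigma),
               stringsAsFactors = FALSE)
  })
}

#' Emit a ChEMBL-like activity table for a synthetic library
#'
#' Each compound becomes one activity record (a censored ">" record for the
#' weakest `frac_gt_relation` of compounds, an exact "=" record otherwise);
#' activity types are sampled with `P(IC50) = frac_ic50` and the remainder
#' split over EC50/Ki/Kd; a `frac_duplicates` subset is emitted twice with a
#' different activity type, and a `frac_salted` subset as salt forms; values
#' are reported in mixed concentration units.
#'
#' @param compounds output of [generate_library()].
#' @param cfg the same [synth_config()].
#' @return data.frame with `compound_id`, `smiles`, `activity_type`,
#'   `relation`, `value`, `units`.
#' @export
assign_activities <- function(compounds, cfg) {
  stopifnot(inherits(cfg, "cs_synth_config"),
            all(c("compound_id", "smiles", "true_pActivity") %in% names(compounds)))
  n <- nrow(compounds)
  .with_seed(cfg$seed + 1L, {
    types <- c("IC50", "EC50", "Ki", "Kd")
    p_rest <- (1 - cfg$frac_ic50) / 3
    atype <- sample(types, n, replace = TRUE,
                    prob = c(cfg$frac_ic50, rep(p_rest, 3)))
    # censored rows: the weakest compounds, reported only as "> bound"
    ncens <- round(cfg$frac_gt_relation * n)
    cens_idx <- order(compounds$true_pActivity)[seq_len(ncens)]
    relation <- rep("=", n)
    relation[cens_idx] <- ">"
    value_nM <- 10^(9 - compounds$true_pActivity)
    value_nM[cens_idx] <- cfg$censor_value_nM
    tab <- data.frame(compound_id = compounds$compound_id,
                      smiles = compounds$smiles,
                      activity_type = atype, relation = relation,
                      value_nM = value_nM, stringsAsFactors = FALSE)
    # duplicate rows: same compound, different activity type, jittered value
    exact <- which(relation == "=")
    ndup <- round(cfg$frac_duplicates * n)
    if (ndup > 0 && length(exact) > 0) {
      di <- sample(exact, min(ndup, length(exact)))
      dup <- tab[di, , drop = FALSE]
      dup$activity_type <- vapply(dup$activity_type, function(t)
        sample(setdiff(types, t), 1L), "")
      dup$value_nM <- 10^(9 - (compounds$true_pActivity[di] +
                                 stats::rnorm(length(di), 0, 0.1)))
      tab <- rbind(tab, dup)
    }
    # salt forms
    nsalt <- round(cfg$frac_salted * nrow(tab))
    if (nsalt > 0) {
      si <- sample(nrow(tab), nsalt)
      tab$smiles[si] <- paste0(tab$smiles[si],
                               sample(c(".Cl", ".[Na+]", ".Cl.Cl"),
                                      nsalt, replace = TRUE))
    }
    # mixed units
    unit <- sample(c("nM", "uM", "M"), nrow(tab), replace = TRUE,
                   prob = c(0.7, 0.25, 0.05))
    value <- tab$value_nM
    value[unit == "uM"] <- value[unit == "uM"] / 1e3
    value[unit == "M"] <- value[unit == "M"] / 1e9
    out <- data.frame(compound_id = tab$compound_id, smiles = tab$smiles,
                      activity_type = tab$activity_type,
                      relation = tab$relation,
                      value = value, units = unit, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Generate drug-like inactive decoys
#'
#' Decoys come from the same grammar but are guaranteed pharmacophore-free by
#' construction, and each passes a drug-likeness filter (MW 200-500, at most
#' 5 H-bond donors, at most 10 acceptors).
#'
#' @param n number of decoys.
#' @param seed integer seed.
#' @return data.frame with `compound_id`, `smiles`, `std_key`.
#' @export
generate_decoys <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  .with_seed(seed, {
    got <- data.frame(smiles = character(0), key = character(0),
                      stringsAsFactors = FALSE)
    tries <- 0L
    while (nrow(got) < n && tries < 80L) {
      tries <- tries + 1L
      k <- max(64L, ceiling((n - nrow(got)) * 1.8))
      cand <- .cs_assemble(k, frac_pharm = 0)
      cand$key <- make_std_key(cand$smiles)
      cand <- cand[!is.na(cand$key), , drop = FALSE]
      pr <- ob_properties(cand$key)
      keep <- !is.na(pr$MW) & pr$MW >= 200 & pr$MW <= 500 &
        pr$HBD <= 5 & pr$HBA1 <= 10
      cand <- cand[keep, , drop = FALSE]
      cand <- cand[!duplicated(cand$key) & !(cand$key %in% got$key), ,
                   drop = FALSE]
      got <- rbind(got, cand[, c("smiles", "key")])
    }
    if (nrow(got) < n)
      stop("could not generate ", n, " drug-like decoys")
    got <- got[seq_len(n), , drop = FALSE]
    data.frame(compound_id = sprintf("DEC%05d", seq_len(n)),
               smiles = got$smiles, std_key = got$key,
               stringsAsFactors = FALSE)
  })
}

#' Write an activity table, decoy library or screening library to disk
#'
#' @param activity data.frame from [assign_activities()]; written as CSV.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(activity, path) {
  utils::write.csv(activity, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity_csv
#' @param compounds data.frame with `smiles` and `compound_id`; written as
#'   whitespace-delimited .smi.
#' @export
write_smi <- function(compounds, path) {
  writeLines(paste(compounds$smiles, compounds$compound_id), path)
  invisible(path)
}
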