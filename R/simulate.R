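#' @include genotype-methods.R
NULL

## One seeded generator per call: run `expr` under `seed` and restore the
## caller's RNG state afterwards, so simulators never leak global state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

#' Build a strain-trait table
#'
#' The package's standard long container for one processed trait value per
#' strain: columns `strain`, `trait`, `condition`, `value`.
#'
#' @param strain character strain ids.
#' @param value numeric trait values.
#' @param trait trait label.
#' @param condition condition label (`"drug"` or `"control"`).
#' @return data.frame with columns `strain`, `trait`, `condition`, `value`.
#' @export
strainTraitTable <- function(strain, value, trait = "trait",
                             condition = "drug") {
  stopifnot(length(strain) == length(value))
  data.frame(strain = as.character(strain), trait = trait,
             condition = condition, value = as.numeric(value))
}

#' Evenly spaced marker map emulating the C. elegans karyotype
#'
#' Six chromosomes (I-V, X) at their approximate physical lengths and a
#' uniform 50 cM genetic length each; markers are spread evenly along each
#' chromosome, allocated proportionally to physical length.
#'
#' @param n_markers total marker count (default 1454, a realistic
#'   RIAIL-panel marker density).
#' @return marker map data.frame (`marker_id`, `chromosome`, `position_bp`,
#'   `genetic_pos_cM`).
#' @examples
#' head(elegansMarkerMap(60))
#' @export
elegansMarkerMap <- function(n_markers = 1454) {
  stopifnot(n_markers >= 6)
  chrom <- c("I", "II", "III", "IV", "V", "X")
  len_bp <- c(15.07e6, 15.28e6, 13.78e6, 17.49e6, 20.92e6, 17.72e6)
  len_cM <- rep(50, 6)
  n_per <- pmax(1L, round(n_markers * len_bp / sum(len_bp)))
  # adjust rounding drift on the largest chromosome
  n_per[5] <- n_per[5] + (n_markers - sum(n_per))
  maps <- lapply(seq_along(chrom), function(k) {
    n <- n_per[k]
    pos <- round(seq(1, len_bp[k], length.out = n))
    pos <- as.integer(pos + seq_len(n) - 1L)  # guard strict monotonicity
    data.frame(marker_id = sprintf("%s_%07d", chrom[k], pos),
               chromosome = chrom[k], position_bp = pos,
               genetic_pos_cM = seq(0, len_cM[k], length.out = n))
  })
  do.call(rbind, maps)
}

#' Simulate recombinant inbred advanced intercross line (RIAIL) genotypes
#'
#' Each line is a homozygous mosaic of the two parental haplotypes.
#' Crossovers are placed as a Poisson process on the genetic map with no
#' interference; the expected breakpoint count per chromosome is the map
#' length in Morgans times `1 + n_intercross_generations`, so selfing-only
#' panels (`n_intercross_generations = 0`) carry one meiosis-equivalent of
#' recombination and advanced intercrossing expands the map linearly.
#'
#' @param n_lines number of inbred lines (>= 2).
#' @param markers marker map data.frame; see [elegansMarkerMap()].
#' @param n_intercross_generations non-negative integer, generations of
#'   random intercrossing before inbreeding (default 10).
#' @param seed integer RNG seed; output is bit-identical for a fixed seed.
#' @return a [GenotypeMatrix-class]; allele 0 is the reference
#'   (Bristol-like) parent, allele 1 the alternate parent.
#' @examples
#' g <- simulateRiailGenotypes(20, elegansMarkerMap(120), seed = 1)
#' g
#' @export
simulateRiailGenotypes <- function(n_lines, markers,
                                   n_intercross_generations = 10,
                                   seed) {
  markers <- sortMarkerMap(as.data.frame(markers))
  msg <- validateMarkerMap(markers)
  if (!isTRUE(msg)) stop(msg)
  if (n_lines < 2) stop("n_lines must be >= 2")
  if (n_intercross_generations < 0)
    stop("n_intercross_generations must be >= 0")
  expansion <- 1 + n_intercross_generations
  bychrom <- split(seq_len(nrow(markers)), markers$chromosome)
  calls <- withSeed(seed, {
    out <- matrix(NA_integer_, n_lines, nrow(markers))
    for (idx in bychrom) {
      cm <- markers$genetic_pos_cM[idx]
      L <- (max(cm) - min(cm)) / 100  # Morgans
      for (i in seq_len(n_lines)) {
        nx <- rpois(1L, L * expansion)
        start <- rbinom(1L, 1L, 0.5)
        if (nx == 0L) {
          out[i, idx] <- start
        } else {
          bp <- runif(nx, min(cm), max(cm))
          crossings <- vapply(cm, function(p) sum(bp < p), numeric(1))
          out[i, idx] <- as.integer((start + crossings) %% 2L)
        }
      }
    }
    out
  })
  rownames(calls) <- sprintf("riail%04d", seq_len(n_lines))
  colnames(calls) <- markers$marker_id
  GenotypeMatrix(calls, markers)
}

#' Simulate a structured panel of wild isolates
#'
#' Balding-Nichols model: each marker draws an ancestral allele frequency
#' uniform on (0.1, 0.9); each subpopulation draws its own frequency from a
#' Beta distribution with divergence parameter `fst_like_divergence`, and
#' inbred strains draw homozygous alleles from their subpopulation
#' frequency. With divergence 0 all subpopulations share the ancestral
#' frequency and the panel is unstructured.
#'
#' By default sites are independent given the subpopulation frequencies
#' (no linkage disequilibrium). Passing `n_founder_haplotypes` instead
#' draws that many founder haplotypes per subpopulation and builds each
#' strain as a recombinant mosaic of founders (switching founder with
#' probability `founder_switch_prob` between adjacent markers, resetting
#' at chromosome boundaries) — a caricature of the long shared haplotypes
#' of a selfing species, giving the panel local LD.
#'
#' @param n_strains number of strains (>= 1); assigned round-robin to
#'   subpopulations.
#' @param markers marker map data.frame.
#' @param n_subpopulations number of subpopulations (>= 1).
#' @param fst_like_divergence Fst-like divergence in `[0, 1)`.
#' @param seed integer RNG seed.
#' @param n_founder_haplotypes optional founder count per subpopulation
#'   (`NULL`, the default, keeps sites independent).
#' @param founder_switch_prob per-interval founder switch probability for
#'   the mosaic mode (default 0.02).
#' @return a [GenotypeMatrix-class]; strain ids `sub<k>_wi<i>` encode the
#'   subpopulation assignment.
#' @export
simulateWildPanel <- function(n_strains, markers, n_subpopulations = 1,
                              fst_like_divergence = 0, seed,
                              n_founder_haplotypes = NULL,
                              founder_switch_prob = 0.02) {
  markers <- sortMarkerMap(as.data.frame(markers))
  msg <- validateMarkerMap(markers)
  if (!isTRUE(msg)) stop(msg)
  if (n_strains < 1) stop("n_strains must be >= 1")
  if (n_subpopulations < 1) stop("n_subpopulations must be >= 1")
  F <- fst_like_divergence
  if (!is.numeric(F) || F < 0 || F >= 1)
    stop("fst_like_divergence must lie in [0, 1)")
  m <- nrow(markers)
  pop <- rep_len(seq_len(n_subpopulations), n_strains)
  calls <- withSeed(seed, {
    p_anc <- runif(m, 0.1, 0.9)
    p_sub <- matrix(rep(p_anc, each = n_subpopulations),
                    n_subpopulations, m)
    if (F > 0) {
      a <- p_anc * (1 - F) / F
      b <- (1 - p_anc) * (1 - F) / F
      for (k in seq_len(n_subpopulations))
        p_sub[k, ] <- rbeta(m, a, b)
    }
    out <- matrix(NA_integer_, n_strains, m)
    if (is.null(n_founder_haplotypes)) {
      for (i in seq_len(n_strains))
        out[i, ] <- rbinom(m, 1L, p_sub[pop[i], ])
    } else {
      stopifnot(n_founder_haplotypes >= 1,
                founder_switch_prob >= 0, founder_switch_prob <= 1)
      chrom <- markers$chromosome
      new_chrom <- c(TRUE, chrom[-1] != chrom[-m])
      founders <- lapply(seq_len(n_subpopulations), function(k)
        matrix(rbinom(n_founder_haplotypes * m, 1L,
                      rep(p_sub[k, ], each = n_founder_haplotypes)),
               n_founder_haplotypes, m))
      for (i in seq_len(n_strains)) {
        switch_here <- new_chrom | (runif(m) < founder_switch_prob)
        idx <- sample.int(n_founder_haplotypes, sum(switch_here),
                          replace = TRUE)
        path <- idx[cumsum(switch_here)]
        out[i, ] <- founders[[pop[i]]][cbind(path, seq_len(m))]
      }
    }
    out
  })
  rownames(calls) <- sprintf("sub%d_wi%04d", pop, seq_len(n_strains))
  colnames(calls) <- markers$marker_id
  GenotypeMatrix(calls, markers)
}

#' Inject missing genotype calls
#'
#' Missingness is off by default in the simulators; this injects it at a
#' stated rate for robustness tests.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param rate per-call missingness probability.
#' @param seed integer RNG seed.
#' @return a [GenotypeMatrix-class] with `NA` calls injected.
#' @export
injectMissing <- function(genotypes, rate, seed) {
  stopifnot(is(genotypes, "GenotypeMatrix"), rate >= 0, rate <= 1)
  calls <- genotypeCalls(genotypes)
  calls[] <- withSeed(seed, {
    drop <- runif(length(calls)) < rate
    replace(as.vector(calls), drop, NA_integer_)
  })
  GenotypeMatrix(calls, markerMap(genotypes))
}

#' Simulate strain phenotypes with planted QTL
#'
#' Builds a trait as a sum of standardized QTL genotype effects with stated
#' variance explained, an optional polygenic term built from all markers,
#' and i.i.d. Gaussian noise filling the remaining variance:
#' \deqn{y = \sum_q \sqrt{VE_q}\, \tilde g_q + \sqrt{h^2_{poly}}\, \tilde u
#'   + \sqrt{1 - \sum_q VE_q - h^2_{poly}}\, \epsilon}
#' where tildes denote standardization to unit variance.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param qtls data.frame with columns `marker_id` and `variance_explained`
#'   (each in (0,1)); may have zero rows for a null trait.
#' @param polygenic_h2 additional polygenic variance fraction in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param standardize if `TRUE` (default) the returned trait is rescaled to
#'   mean 0, variance 1.
#' @param trait,condition labels for the output table.
#' @return strain-trait table (see [strainTraitTable()]).
#' @export
simulatePhenotypes <- function(genotypes, qtls = NULL, polygenic_h2 = 0,
                               seed, standardize = TRUE, trait = "trait",
                               condition = "drug") {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  if (is.null(qtls)) qtls <- data.frame(marker_id = character(),
                                        variance_explained = numeric())
  ve <- qtls$variance_explained
  if (any(ve <= 0 | ve >= 1)) stop("variance_explained must lie in (0, 1)")
  if (sum(ve) + polygenic_h2 > 1)
    stop("variance fractions sum to more than 1")
  calls <- genotypeCalls(genotypes)
  bad <- setdiff(qtls$marker_id, colnames(calls))
  if (length(bad)) stop("QTL markers absent from genotypes: ",
                        paste(bad, collapse = ", "))
  n <- nrow(calls)
  y <- withSeed(seed, {
    out <- numeric(n)
    for (k in seq_len(nrow(qtls))) {
      g <- calls[, qtls$marker_id[k]]
      if (sd(g, na.rm = TRUE) == 0)
        stop("QTL marker ", qtls$marker_id[k], " is monomorphic")
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      out <- out + sqrt(ve[k]) * as.vector(scale(g))
    }
    if (polygenic_h2 > 0) {
      Z <- calls
      Z[is.na(Z)] <- matrix(colMeans(Z, na.rm = TRUE),
                            n, ncol(Z), byrow = TRUE)[is.na(Z)]
      u <- as.vector(scale(Z) %*% rnorm(ncol(Z)))
      u[is.na(u)] <- 0
      if (sd(u) > 0) out <- out + sqrt(polygenic_h2) * u / sd(u) else
        out <- out
    }
    resid_frac <- 1 - sum(ve) - polygenic_h2
    if (resid_frac > 0) out <- out + sqrt(resid_frac) * rnorm(n)
    out
  })
  if (standardize && sd(y) > 0) y <- as.vector(scale(y))
  strainTraitTable(strainNames(genotypes), y, trait = trait,
                   condition = condition)
}

#' Simulate sorter-style well records
#'
#' Emulates a plate-based high-throughput fitness assay: a few L4 animals
#' are sorted per well, their progeny's body lengths (TOF units) and brood
#' counts are scored four days later. Drug wells carry the strain effect
#' plus a shared per-assay shift; control (vehicle-only) wells carry a
#' correlated baseline with coupling coefficient `control_coupling`. Paired
#' drug/control wells exist for every strain x assay.
#'
#' @param strain_effects strain-trait table of true strain effects in TOF
#'   units (deviations around the drug baseline).
#' @param n_assays number of assay blocks (>= 1, default 3).
#' @param assay_shift_sd SD of the per-assay additive shift (TOF units).
#' @param control_coupling coefficient carrying the strain effect into the
#'   control condition.
#' @param animals_per_well animals scored per well (default 50).
#' @param noise_sd within-well animal-length SD (TOF units, default 15).
#' @param sorted_n animals sorted into each well (default 3).
#' @param drug_name drug label stamped on drug wells.
#' @param seed integer RNG seed.
#' @return data.frame of well records: `assay_id`, `plate`, `well`,
#'   `strain`, `condition`, `drug_name`, `sorted_n`, `animal_lengths`
#'   (list column), `brood_count`, `fluorescence`, `exclude`.
#' @export
simulateWellData <- function(strain_effects, n_assays = 3,
                             assay_shift_sd = 10, control_coupling = 0.3,
                             animals_per_well = 50, noise_sd = 15,
                             sorted_n = 3, drug_name = "etoposide", seed) {
  if (n_assays < 1) stop("n_assays must be >= 1")
  if (animals_per_well < 1) stop("animals_per_well must be >= 1")
  strains <- strain_effects$strain
  eff <- setNames(strain_effects$value, strains)
  drug_base <- 250
  ctrl_base <- 330
  withSeed(seed, {
    rows <- list()
    wells96 <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
    for (a in seq_len(n_assays)) {
      shift <- rnorm(1, 0, assay_shift_sd)
      for (s in seq_along(strains)) {
        for (cond in c("drug", "control")) {
          mu <- if (cond == "drug") drug_base + eff[s] + shift else
            ctrl_base + control_coupling * eff[s] + shift
          lengths <- pmax(rnorm(animals_per_well, mu, noise_sd), 1)
          brood <- rpois(1, if (cond == "drug") 60 else 120)
          rows[[length(rows) + 1L]] <- data.frame(
            assay_id = sprintf("a%02d", a),
            plate = sprintf("p%02d", (s - 1L) %/% 96L + 1L),
            well = wells96[(s - 1L) %% 96L + 1L],
            strain = strains[s], condition = cond,
            drug_name = if (cond == "drug") drug_name else "DMSO",
            sorted_n = sorted_n,
            animal_lengths = I(list(lengths)),
            brood_count = brood,
            fluorescence = abs(rnorm(1, 0, 0.1)),
            exclude = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Closed-form selection recursion for an edited allele
#'
#' Deterministic expectation of the edited-cell fraction after `g`
#' generations of growth at relative fitness `w`:
#' \eqn{f' = f w^g / (f w^g + 1 - f)}.
#'
#' @param f starting edited fraction in (0, 1).
#' @param w relative fitness of edited cells (> 0).
#' @param g number of generations (real, >= 0).
#' @return expected post-selection edited fraction.
#' @export
selectionRecursion <- function(f, w, g) {
  stopifnot(f > 0, f < 1, w > 0, g >= 0)
  f * w^g / (f * w^g + 1 - f)
}

#' Simulate pooled amplicon read counts under selection
#'
#' Emulates a pooled genome-editing experiment: an edited allele at a small
#' starting fraction is grown under drug selection (relative fitness
#' `relative_fitness_edited` per generation) or under no-drug control
#' conditions (fitness 1); reads are drawn binomially at the stated depth
#' for pre- and post-selection timepoints in both arms.
#'
#' @param edit_fraction_pre starting edited fraction in (0, 1).
#' @param relative_fitness_edited per-generation relative fitness of the
#'   edited allele under drug (1 = neutral).
#' @param n_generations generations of growth (real).
#' @param depth sequencing depth per sample (> 0).
#' @param seed integer RNG seed.
#' @param locus locus label (default `"TOP2A"`).
#' @param condition drug-condition label (default `"etoposide"`).
#' @return read-count table: `locus`, `condition`, `timepoint`,
#'   `wildtype_reads`, `edited_reads`.
#' @export
simulatePooledReadcounts <- function(edit_fraction_pre,
                                     relative_fitness_edited = 1,
                                     n_generations = 10, depth, seed,
                                     locus = "TOP2A",
                                     condition = "etoposide") {
  if (!is.numeric(depth) || depth <= 0) stop("depth must be > 0")
  if (edit_fraction_pre <= 0 || edit_fraction_pre >= 1)
    stop("edit_fraction_pre must lie in (0, 1)")
  f_pre <- edit_fraction_pre
  f_drug <- selectionRecursion(f_pre, relative_fitness_edited, n_generations)
  f_ctrl <- selectionRecursion(f_pre, 1, n_generations)  # = f_pre
  withSeed(seed, {
    draw <- function(f) {
      e <- rbinom(1L, as.integer(depth), f)
      c(wildtype = as.integer(depth) - e, edited = e)
    }
    pre1 <- draw(f_pre); post1 <- draw(f_drug)
    pre0 <- draw(f_pre); post0 <- draw(f_ctrl)
    data.frame(
      locus = locus,
      condition = c(condition, condition, "no_drug", "no_drug"),
      timepoint = c("pre", "post", "pre", "post"),
      wildtype_reads = c(pre1[1], post1[1], pre0[1], post0[1]),
      edited_reads = c(pre1[2], post1[2], pre0[2], post0[2]))
  })
}
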