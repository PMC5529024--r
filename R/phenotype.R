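#' @include simulate.R
NULL

#' Summarize well records into quantile traits
#'
#' For each scored well, computes the 10th, 25th, 50th, 75th and 90th
#' quantiles of animal length (linear-interpolation quantile definition,
#' `stats::quantile` type 7) and the brood count normalized by the number
#' of animals originally sorted into the well (`norm_n`). Wells flagged
#' `exclude` (the package's explicit stand-in for bubble/contamination
#' filtering) are dropped.
#'
#' @param wells data.frame of well records as produced by
#'   [simulateWellData()] or [readWellRecords()].
#' @return data.frame with the well keys (`assay_id`, `plate`, `well`,
#'   `strain`, `condition`, `drug_name`) plus `q10`, `q25`, `q50`, `q75`,
#'   `q90`, `norm_n`.
#' @export
summarizeWells <- function(wells) {
  keys <- c("assay_id", "plate", "well", "strain", "condition", "drug_name")
  if (NROW(wells) == 0L) {
    cols <- c(as.list(setNames(rep(list(character(0)), length(keys)), keys)),
              setNames(rep(list(numeric(0)), 6),
                       c("q10", "q25", "q50", "q75", "q90", "norm_n")))
    return(as.data.frame(cols))
  }
  if ("exclude" %in% names(wells)) wells <- wells[!wells$exclude, ]
  if (any(wells$sorted_n <= 0)) stop("wells with sorted_n <= 0")
  lens <- wells$animal_lengths
  if (any(lengths(lens) == 0L)) stop("scored wells must have >= 1 animal length")
  qs <- t(vapply(lens, quantile,
                 probs = c(0.1, 0.25, 0.5, 0.75, 0.9),
                 type = 7, names = FALSE, FUN.VALUE = numeric(5)))
  out <- wells[keys]
  out$q10 <- qs[, 1]; out$q25 <- qs[, 2]; out$q50 <- qs[, 3]
  out$q75 <- qs[, 4]; out$q90 <- qs[, 5]
  out$norm_n <- wells$brood_count / wells$sorted_n
  rownames(out) <- NULL
  out
}

#' Remove assay-to-assay shifts by linear regression
#'
#' Fits `value ~ assay_id` by least squares on the assay indicator
#' variables and returns the residuals; with a single assay level this
#' degenerates to centering. Residuals sum to zero within each assay.
#'
#' @param traits data.frame with a numeric `value` column and a categorical
#'   `assay_id` column; all other columns pass through.
#' @return `traits` with `value` replaced by the assay-regressed residuals.
#' @export
regressAssay <- function(traits) {
  stopifnot(is.data.frame(traits), all(c("value", "assay_id") %in% names(traits)))
  if (nrow(traits) < 2) stop("need >= 2 wells to regress assay effects")
  if (length(unique(traits$assay_id)) == 1L) {
    traits$value <- traits$value - mean(traits$value)
  } else {
    fit <- lm(value ~ factor(assay_id), data = traits)
    traits$value <- as.numeric(resid(fit))
  }
  traits
}

#' Prune extreme strain values (single-pass IQR rule)
#'
#' Flags values strictly greater than `Q75 + 2 IQR` or strictly less than
#' `Q25 - 2 IQR`, with quartiles computed once on the full input. If more
#' than `escape_fraction` (default 5%) of the strains lie outside that
#' range, nothing is removed: mass exceedance is taken as real signal, not
#' outliers (at the exact boundary — one flagged strain of twenty —
#' pruning still applies). The rule is applied once, never iterated.
#'
#' @param values numeric vector of per-strain trait values (names kept).
#' @param escape_fraction fraction of flagged strains at which pruning is
#'   abandoned (default 0.05).
#' @return list with `values` (the retained values) and `removed` (logical
#'   flags aligned with the input).
#' @export
pruneOutliers <- function(values, escape_fraction = 0.05) {
  n <- length(values)
  if (n < 4) {
    warning("fewer than 4 values: no pruning applied")
    return(list(values = values, removed = rep(FALSE, n)))
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  removed <- !is.na(values) &
    (values > q[2] + 2 * iqr | values < q[1] - 2 * iqr)
  if (sum(removed) > escape_fraction * n)
    removed <- rep(FALSE, n)
  list(values = values[!removed], removed = removed)
}

#' Regress drug traits on paired control traits
#'
#' Fits `drug ~ control` across strains by simple least squares and
#' returns per-strain residuals, removing any component of the drug
#' response predictable from control (vehicle-only) growth. Residuals are
#' exactly uncorrelated with the control values.
#'
#' @param drug_traits,control_traits strain-trait tables
#'   (see [strainTraitTable()]); strains are matched by id, unmatched
#'   strains dropped with a warning.
#' @return strain-trait table of residual drug traits (condition label
#'   preserved from `drug_traits`).
#' @export
regressControl <- function(drug_traits, control_traits) {
  shared <- intersect(drug_traits$strain, control_traits$strain)
  unmatched <- length(unique(c(drug_traits$strain, control_traits$strain))) -
    length(shared)
  if (unmatched > 0)
    warning(unmatched, " unmatched strain(s) dropped")
  if (length(shared) < 3) stop("fewer than 3 matched strains")
  d <- drug_traits$value[match(shared, drug_traits$strain)]
  c0 <- control_traits$value[match(shared, control_traits$strain)]
  if (sd(c0) == 0) {
    res <- d - mean(d)
  } else {
    res <- as.numeric(resid(lm(d ~ c0)))
  }
  strainTraitTable(shared, res,
                   trait = drug_traits$trait[1],
                   condition = drug_traits$condition[1])
}

#' Broad-sense heritability from replicated strain measurements
#'
#' Fits the one-way random-effects model `value ~ 1 + (1|strain)` by REML
#' (via \pkg{lme4}) and returns
#' \eqn{H^2 = \sigma^2_{strain} / (\sigma^2_{strain} + \sigma^2_{resid})}.
#' A negative genetic variance cannot occur under REML (it is bounded at
#' zero); if the total variance is zero, \eqn{H^2 = 0} by convention and
#' the estimate is flagged. For balanced designs the estimate agrees with
#' the ANOVA moment estimator `(MSB - MSW)/k` within numerical tolerance.
#'
#' @param data data.frame with columns `strain` and `value` (one row per
#'   replicate measurement).
#' @return a [HeritabilityEstimate-class].
#' @examples
#' d <- data.frame(strain = rep(c("a", "b"), each = 3),
#'                 value = c(1, 1, 1, 2, 2, 2))
#' estimateHeritability(d)
#' @export
estimateHeritability <- function(data) {
  stopifnot(all(c("strain", "value") %in% names(data)))
  data <- data[!is.na(data$value), ]
  if (length(unique(data$strain)) < 2) stop("need >= 2 strains")
  if (max(table(data$strain)) < 2)
    stop("need >= 2 replicates for at least one strain")
  if (var(data$value) == 0)
    return(new("HeritabilityEstimate", H2 = 0, varStrain = 0, varResid = 0,
               note = "zero total variance"))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(value ~ 1 + (1 | strain), data = data, REML = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    vs <- vc$vcov[vc$grp == "strain"]
    ve <- vc$vcov[vc$grp == "Residual"]
  } else {
    # moment-estimator fallback for degenerate fits
    k <- mean(table(data$strain))
    a <- anova(aov(value ~ factor(strain), data = data))
    msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
    vs <- max((msb - msw) / k, 0); ve <- msw
  }
  vs <- max(vs, 0); ve <- max(ve, 0)
  tot <- vs + ve
  new("HeritabilityEstimate",
      H2 = if (tot > 0) vs / tot else 0,
      varStrain = vs, varResid = ve,
      note = if (tot > 0) "" else "zero total variance")
}

#' Gate heterozygotes by fluorescence
#'
#' Animals are labeled heterozygous when their fluorescence lies strictly
#' between the dark-parent upper gate (95th percentile of the
#' non-fluorescent parent) and the bright-parent lower gate (5th percentile
#' of the fluorescent parent); values at or below the dark gate are
#' `parental_dark`, at or above the bright gate `parental_bright`.
#'
#' @param fluorescence per-animal fluorescence values to classify.
#' @param bright_parent,dark_parent reference fluorescence distributions of
#'   the two parental strains (non-empty).
#' @param gate_probs length-2 numeric: percentile of the dark parent used
#'   as lower gate and of the bright parent used as upper gate (default
#'   `c(0.95, 0.05)`).
#' @return character vector of labels in
#'   \{`"het"`, `"parental_bright"`, `"parental_dark"`\}.
#' @export
classifyHeterozygotes <- function(fluorescence, bright_parent, dark_parent,
                                  gate_probs = c(0.95, 0.05)) {
  if (length(bright_parent) == 0 || length(dark_parent) == 0)
    stop("both parental reference distributions must be non-empty")
  dark_gate <- quantile(dark_parent, gate_probs[1], type = 7, names = FALSE)
  bright_gate <- quantile(bright_parent, gate_probs[2], type = 7,
                          names = FALSE)
  if (dark_gate >= bright_gate)
    stop("parental fluorescence gates overlap (dark 95th >= bright 5th); ",
         "supply manual gates")
  ifelse(fluorescence > dark_gate & fluorescence < bright_gate, "het",
         ifelse(fluorescence <= dark_gate, "parental_dark",
                "parental_bright"))
}

#' Pairwise strain comparisons (ANOVA + Tukey HSD)
#'
#' One-way ANOVA `value ~ strain` followed by Tukey's honest significant
#' difference on the studentized-range distribution. Unbalanced groups are
#' handled by the Tukey-Kramer harmonic-mean correction (the behaviour of
#' `stats::TukeyHSD`).
#'
#' @param traits data.frame with columns `strain` and `value`, replicated
#'   per strain.
#' @return data.frame with one row per strain pair: `comparison`, `diff`,
#'   `lwr`, `upr`, `p_adj` (family-wise adjusted, in `[0, 1]`).
#' @export
compareStrains <- function(traits) {
  stopifnot(all(c("strain", "value") %in% names(traits)))
  tab <- table(traits$strain)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 strains with >= 2 replicates each")
  fit <- aov(value ~ factor(strain), data = traits)
  tk <- TukeyHSD(fit)[[1]]
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = pmin(pmax(tk[, "p adj"], 0), 1),
             row.names = NULL)
}

#' Run the full trait-processing pipeline on well records
#'
#' Fixed stage order, mirroring the assay-processing narrative:
#' summarize wells, regress out assay effects (per condition), aggregate
#' to strain means, prune outliers (single-pass IQR rule), then regress
#' the drug trait on the control trait. The prune/control order can be
#' swapped via `prune_before_control = FALSE`.
#'
#' @param wells well records data.frame.
#' @param trait which well summary to process (default `"q50"`, the median
#'   animal length).
#' @param prune_before_control logical; default `TRUE`.
#' @return strain-trait table of processed (residual) trait values.
#' @export
processWellTraits <- function(wells, trait = "q50",
                              prune_before_control = TRUE) {
  ws <- summarizeWells(wells)
  ws$value <- ws[[trait]]
  ws <- regressAssay(ws)
  agg <- function(cond) {
    sub <- ws[ws$condition == cond, ]
    v <- tapply(sub$value, sub$strain, mean)
    strainTraitTable(names(v), as.numeric(v), trait = trait,
                     condition = cond)
  }
  drug <- agg("drug"); ctrl <- agg("control")
  doPrune <- function(tt) {
    pr <- pruneOutliers(setNames(tt$value, tt$strain))
    tt[!pr$removed, , drop = FALSE]
  }
  if (prune_before_control) {
    drug <- doPrune(drug)
    regressControl(drug, ctrl)
  } else {
    doPrune(regressControl(drug, ctrl))
  }
}
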