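#' @include popgen.R
NULL

#' Exact-match allele counting
#'
#' A read increments the wild-type or edited counter only on an exact
#' full-span match to the respective reference sequence; every other read
#' (indels, sequencing errors, partial matches) is counted as unmatched.
#' No alignment is performed — exact matching is the design, not a
#' shortcut, because the edit is a known substitution in a fixed
#' amplicon.
#'
#' @param reads character vector of read sequences.
#' @param wildtype_ref,edited_ref reference sequences; must differ.
#' @return named integer vector `c(wildtype, edited, unmatched)`.
#' @examples
#' countAlleles(c("ACGT", "ACTT", "AGGT"), "ACGT", "ACTT")
#' @export
countAlleles <- function(reads, wildtype_ref, edited_ref) {
  if (identical(wildtype_ref, edited_ref))
    stop("wild-type and edited references are identical")
  wt <- sum(reads == wildtype_ref)
  ed <- sum(reads == edited_ref)
  c(wildtype = wt, edited = ed, unmatched = length(reads) - wt - ed)
}

#' Edited-allele enrichment between two conditions
#'
#' Contrasts the edited-allele fraction of a treated sample against a
#' control sample:
#' `fold_change = [edited/(edited+wt)]_treated / [edited/(edited+wt)]_control`,
#' with a two-sided Fisher's exact test on the 2x2 count table
#' (edited/wild-type x treated/control); the two-sided p-value sums the
#' probabilities of all tables with fixed margins no more likely than the
#' observed one (the minimum-likelihood rule, the dominant convention).
#' Swapping treated and control inverts the fold change.
#'
#' @param treated,control length-2 numeric vectors
#'   `c(wildtype, edited)` of read counts; both totals must be positive.
#' @param locus,condition labels echoed into the result.
#' @return one-row data.frame: `locus`, `condition`, `fold_change`
#'   (`NaN`, flagged in `note`, when the control edited fraction is 0),
#'   `odds_ratio` (conditional MLE), `p_value`, and the four counts.
#' @examples
#' enrichmentTest(treated = c(950, 50), control = c(995, 5))
#' @export
enrichmentTest <- function(treated, control, locus = NA_character_,
                           condition = NA_character_) {
  stopifnot(length(treated) == 2, length(control) == 2,
            all(treated >= 0), all(control >= 0))
  if (sum(treated) == 0 || sum(control) == 0)
    stop("both conditions need positive read totals")
  ft <- treated[2] / sum(treated)
  fc <- control[2] / sum(control)
  fold <- if (fc == 0) NaN else ft / fc
  tab <- matrix(c(treated[2], treated[1], control[2], control[1]), 2, 2,
                dimnames = list(allele = c("edited", "wildtype"),
                                arm = c("treated", "control")))
  fe <- fisher.test(tab, alternative = "two.sided")
  data.frame(locus = locus, condition = condition,
             fold_change = unname(fold),
             odds_ratio = unname(fe$estimate),
             p_value = fe$p.value,
             treated_wildtype = treated[1], treated_edited = treated[2],
             control_wildtype = control[1], control_edited = control[2],
             note = if (fc == 0) "control edited fraction is 0" else "")
}

#' Enrichment statistics from a read-count table
#'
#' Applies [enrichmentTest()] per locus and drug condition of a pooled
#' read-count table. The headline contrast (`"post_vs_control"`,
#' default) compares each drug's post-treatment counts with the no-drug
#' post-treatment counts; `"post_vs_pre"` compares each condition's post
#' counts with its own pre counts.
#'
#' @param readcounts read-count table (`locus`, `condition`, `timepoint`,
#'   `wildtype_reads`, `edited_reads`); see
#'   [simulatePooledReadcounts()] / [readReadCounts()].
#' @param contrast `"post_vs_control"` (default) or `"post_vs_pre"`.
#' @param control_condition label of the no-drug arm (default
#'   `"no_drug"`).
#' @return data.frame of [enrichmentTest()] rows.
#' @export
enrichmentFromTable <- function(readcounts,
                                contrast = c("post_vs_control",
                                             "post_vs_pre"),
                                control_condition = "no_drug") {
  contrast <- match.arg(contrast)
  getrow <- function(locus, cond, tp) {
    r <- readcounts[readcounts$locus == locus &
                      readcounts$condition == cond &
                      readcounts$timepoint == tp, ]
    if (nrow(r) != 1) stop(sprintf("missing counts for %s/%s/%s",
                                   locus, cond, tp))
    c(r$wildtype_reads, r$edited_reads)
  }
  out <- list()
  for (locus in unique(readcounts$locus)) {
    conds <- setdiff(unique(
      readcounts$condition[readcounts$locus == locus]), control_condition)
    for (cond in conds) {
      treated <- getrow(locus, cond, "post")
      ctrl <- if (contrast == "post_vs_control")
        getrow(locus, control_condition, "post") else
          getrow(locus, cond, "pre")
      out[[length(out) + 1L]] <-
        enrichmentTest(treated, ctrl, locus = locus, condition = cond)
    }
  }
  do.call(rbind, out)
}

#' Monte-Carlo power to detect edited-allele depletion
#'
#' Simulates paired treated/control sequencing experiments in which the
#' treated arm's edited fraction is depleted `effect`-fold relative to
#' the control's `pre_fraction`, and returns the fraction of replicates
#' in which [enrichmentTest()] rejects at `alpha`. Quantifies the
#' detection limit of rare-edit depletion: at sub-percent editing
#' efficiency, even deep sequencing has little power.
#'
#' @param pre_fraction edited fraction in the control arm, in (0, 1).
#' @param depth reads per arm.
#' @param effect fold depletion of the treated arm's edited fraction
#'   (1 = null).
#' @param n_reps Monte-Carlo replicates (default 200).
#' @param seed integer RNG seed.
#' @param alpha test level (default 0.05).
#' @return power estimate in `[0, 1]`, with attribute `"p_values"`.
#' @export
detectDepletionPower <- function(pre_fraction, depth, effect,
                                 n_reps = 200, seed, alpha = 0.05) {
  stopifnot(pre_fraction > 0, pre_fraction < 1, depth > 0, effect > 0)
  f_treated <- pre_fraction / effect
  pvals <- withSeed(seed, {
    vapply(seq_len(n_reps), function(i) {
      et <- rbinom(1L, as.integer(depth), f_treated)
      ec <- rbinom(1L, as.integer(depth), pre_fraction)
      enrichmentTest(c(depth - et, et), c(depth - ec, ec))$p_value
    }, numeric(1))
  })
  structure(mean(pvals < alpha), p_values = pvals)
}
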