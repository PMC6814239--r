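# Conversion of a criteria set into (a) the categorical ACMG class via the
# Richards et al. 2015 combining rules and (b) a continuous posterior
# probability of pathogenicity via the Bayesian points framework of
# Tavtigian et al., in which evidence strengths are exponents of a common
# odds of pathogenicity for a very strong criterion.

#' Parameters of the Bayesian pathogenicity model
#'
#' @param prior Prior probability of pathogenicity (default 0.10).
#' @param odds_pvst Odds of pathogenicity attributed to one very strong
#'   criterion (default 350).
#' @param exponent_scale Scale factor X between adjacent strength levels
#'   (default 2): supporting, moderate and strong evidence weigh
#'   1/X^3, 1/X^2 and 1/X of a very strong criterion, i.e. denominators
#'   8/4/2/1 at the default.
#' @return A `model_params` list.
#' @export
model_params <- function(prior = 0.10, odds_pvst = 350, exponent_scale = 2) {
  if (!(prior > 0 && prior < 1)) {
    rlang::abort("prior must lie strictly between 0 and 1",
                 class = "acmgscore_config_error")
  }
  if (!(odds_pvst > 1)) {
    rlang::abort("odds_pvst must exceed 1", class = "acmgscore_config_error")
  }
  if (!(exponent_scale >= 2)) {
    rlang::abort("exponent_scale must be >= 2", class = "acmgscore_config_error")
  }
  structure(list(prior = prior, odds_pvst = odds_pvst,
                 exponent_scale = exponent_scale),
            class = "model_params")
}

#' Posterior-probability decision thresholds
#'
#' Lenient defaults 0.80 / 0.35; the stricter alternative supported by the
#' validation analyses is 0.85 / 0.20. Comparisons are inclusive.
#' @param pathogenic Posterior at or above which the verdict is
#'   pathogenic-side (default 0.80).
#' @param benign Posterior at or below which the verdict is benign-side
#'   (default 0.35).
#' @return A named list.
#' @export
prob_thresholds <- function(pathogenic = 0.80, benign = 0.35) {
  if (!(benign > 0 && benign < pathogenic && pathogenic < 1)) {
    rlang::abort("thresholds must satisfy 0 < benign < pathogenic < 1",
                 class = "acmgscore_config_error")
  }
  list(pathogenic = pathogenic, benign = benign)
}

#' Tally a criteria set into evidence-strength counts
#'
#' PVS1 is very strong; PS1-PS4 strong; PM1-PM6 moderate; PP1-PP5
#' supporting; BS1-BS4 strong benign; BP1-BP7 supporting benign; BA1 is
#' tracked as the stand-alone flag.
#'
#' @param criteria Character vector of criterion labels.
#' @return A named list of counts
#'   (`n_pvs`, `n_ps`, `n_pm`, `n_pp`, `n_bs`, `n_bp`, `ba1`).
#' @export
evidence_counts <- function(criteria) {
  criteria <- unique(criteria)
  list(
    n_pvs = sum(criteria == "PVS1"),
    n_ps  = sum(grepl("^PS[0-9]$", criteria)),
    n_pm  = sum(grepl("^PM[0-9]$", criteria)),
    n_pp  = sum(grepl("^PP[0-9]$", criteria)),
    n_bs  = sum(grepl("^BS[0-9]$", criteria)),
    n_bp  = sum(grepl("^BP[0-9]$", criteria)),
    ba1   = "BA1" %in% criteria
  )
}

#' Categorical ACMG class from evidence counts
#'
#' Implements the Richards et al. combining rules. Stand-alone BA1 wins
#' over everything else; when both a pathogenic-side and a benign-side rule
#' fire, the evidence is contradictory and the class is VUS.
#'
#' @param e Evidence counts, see [evidence_counts()].
#' @return One of `"pathogenic"`, `"likely_pathogenic"`, `"VUS"`,
#'   `"likely_benign"`, `"benign"`.
#' @export
combine_categorical <- function(e) {
  if (isTRUE(e$ba1)) return("benign")
  path <- with(e,
    (n_pvs >= 1 && (n_ps >= 1 || n_pm >= 2 || (n_pm == 1 && n_pp == 1) || n_pp >= 2)) ||
    n_ps >= 2 ||
    (n_ps == 1 && (n_pm >= 3 || (n_pm == 2 && n_pp >= 2) || (n_pm == 1 && n_pp >= 4))))
  lpath <- with(e,
    (n_pvs == 1 && n_pm == 1) ||
    (n_ps == 1 && n_pm %in% c(1, 2)) ||
    (n_ps == 1 && n_pp >= 2) ||
    n_pm >= 3 || (n_pm == 2 && n_pp >= 2) || (n_pm == 1 && n_pp >= 4))
  ben <- e$n_bs >= 2
  lben <- (e$n_bs == 1 && e$n_bp == 1) || e$n_bp >= 2
  p_side <- path || lpath
  b_side <- ben || lben
  if (p_side && b_side) return("VUS")
  if (path) return("pathogenic")
  if (lpath) return("likely_pathogenic")
  if (ben) return("benign")
  if (lben) return("likely_benign")
  "VUS"
}

#' Posterior probability of pathogenicity
#'
#' Combined odds of pathogenicity:
#' `OddsPath = odds_pvst ^ (n_pp/X^3 + n_pm/X^2 + n_ps/X + n_pvs
#'             - n_bp/X^3 - n_bs/X)`,
#' and `posterior = OddsPath * prior / ((OddsPath - 1) * prior + 1)`.
#' Benign evidence enters the same exponent with negative sign, so net
#' benign evidence pulls the posterior below the prior. Stand-alone BA1
#' forces the posterior to 0. The exponent is evaluated in log space and
#' saturates safely for extreme evidence loads.
#'
#' @param e Evidence counts, see [evidence_counts()].
#' @param params Model parameters, see [model_params()].
#' @return List with `odds_path` and `posterior`.
#' @export
posterior_probability <- function(e, params = model_params()) {
  if (isTRUE(e$ba1)) {
    return(list(odds_path = 0, posterior = 0))
  }
  X <- params$exponent_scale
  expo <- e$n_pp / X^3 + e$n_pm / X^2 + e$n_ps / X + e$n_pvs -
    e$n_bp / X^3 - e$n_bs / X
  log_op <- expo * log(params$odds_pvst)
  if (log_op > 700) return(list(odds_path = Inf, posterior = 1))
  if (log_op < -700) return(list(odds_path = 0, posterior = 0))
  op <- exp(log_op)
  post <- op * params$prior / ((op - 1) * params$prior + 1)
  list(odds_path = op, posterior = post)
}

#' Classify one criteria set
#'
#' Combines the categorical rules and the posterior probability, then
#' applies the probability thresholds (inclusive on both sides).
#'
#' @param criteria Character vector of criterion labels.
#' @param params Model parameters, see [model_params()].
#' @param thresholds See [prob_thresholds()].
#' @return List with `category`, `posterior`, `odds_path` and
#'   `prob_verdict` (`"pathogenic"`, `"benign"` or `"unknown"`).
#' @export
classify_criteria <- function(criteria, params = model_params(),
                              thresholds = prob_thresholds()) {
  e <- evidence_counts(criteria)
  pp <- posterior_probability(e, params)
  category <- combine_categorical(e)
  verdict <- if (pp$posterior >= thresholds$pathogenic) "pathogenic"
             else if (pp$posterior <= thresholds$benign) "benign"
             else "unknown"
  list(category = category, posterior = pp$posterior,
       odds_path = pp$odds_path, prob_verdict = verdict)
}
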