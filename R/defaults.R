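#' Default lifetime-model configurations
#'
#' Ready-made parameter sets for the cohort simulator. The immune offsets
#' are pinned to the printed values `s_min = n p0 + 262` and
#' `s_max = n p0 + 354` cells/day; the remaining magnitudes (`n`, `p0`,
#' `delta`, `T`, `nu`, `r`, `K`) are package defaults calibrated once so
#' that the breast-like Case-1 cumulative risk by age 51 and the Case-3
#' lifetime risk land on the few-percent / ~13% scales of real registry
#' data. They are placeholders in the sense that the exact values used
#' for the published figures are not printed in the main text; see the
#' package vignette.
#'
#' `breast_config()` uses the cycling immune response (Cases 1-3);
#' `colorectal_config()` uses a constant immune response (`case = 0`),
#' which produces the exponential-like cumulative risk typical of most
#' cancers.
#'
#' @param case immune scenario: 0 = constant `s_max`, 1 = fixed menopause
#'   at 51 y, 2 = normally distributed menopause, 3 = distributed
#'   menopause plus HRT.
#' @return a config list with elements `growth`, `mutation`, `immune`,
#'   `case`, `horizon_years`, `fixed_follicular_days`.
#' @export
breast_config <- function(case = 3) {
  n <- 4e7; p0 <- 8.25e-4                   # n*p0 = 33000 mutations/day
  list(
    growth = growth_params("erm2", nu = 1, r = 0.1, mu = 1e-10, s = 0),
    mutation = mutation_params(n = n, p0 = p0, delta = 0.5,
                               life_expectancy_years = 82),
    immune = immune_params(s_min = n * p0 + 262, s_max = n * p0 + 354),
    case = case,
    horizon_years = 85,
    fixed_follicular_days = NULL)
}

#' @rdname breast_config
#' @export
colorectal_config <- function() {
  # constant immune response s(t) = s_max: the typical-cancer
  # configuration has no cycle structure, only the slow drift of the
  # mutation probability moving the (fluctuating) threshold
  breast_config(case = 0)
}
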