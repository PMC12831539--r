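#' Neuropsychological battery specification
#'
#' Metadata for the nine-test battery: scoring direction, legal score
#' range, whether an alternate form is used at retest, and membership in
#' the six-test composite practice-effect score.
#'
#' The two Trail Making tests are timed, so lower scores are better; every
#' other test counts correct responses, so higher is better. The composite
#' averages the oriented SRB z-scores of LNST, SDMT, SFT, JoLO and the two
#' HVLT-R recall scores; BNT and the TMT pair never contribute. SFT
#' (animals named in 60 s) has no instrument ceiling.
#'
#' @return A data frame with one row per test and columns
#'   \code{test}, \code{direction} (\code{"higher_is_better"} or
#'   \code{"lower_is_better"}), \code{score_min}, \code{score_max}
#'   (\code{Inf} for unbounded), \code{alternate_form}, and
#'   \code{composite_member}.
#' @examples
#' battery_specs()
#' @export
battery_specs <- function() {
  data.frame(
    test = c("LNST", "BNT", "SDMT", "SFT", "JoLO",
             "TMT_A", "TMT_B", "HVLT_immediate", "HVLT_delayed"),
    direction = c("higher_is_better", "higher_is_better", "higher_is_better",
                  "higher_is_better", "higher_is_better",
                  "lower_is_better", "lower_is_better",
                  "higher_is_better", "higher_is_better"),
    score_min = c(0, 0, 0, 0, 0, 10, 15, 0, 0),
    score_max = c(21, 60, 110, Inf, 15, 300, 300, 36, 12),
    alternate_form = c(FALSE, FALSE, TRUE, FALSE, TRUE,
                       FALSE, FALSE, TRUE, TRUE),
    composite_member = c(TRUE, FALSE, TRUE, TRUE, TRUE,
                         FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Names of the battery tests
#'
#' @return Character vector of the nine test identifiers.
#' @export
battery_tests <- function() battery_specs()$test

#' Look up the specification row for one test
#'
#' @param test A single test identifier.
#' @return A one-row data frame from \code{\link{battery_specs}}.
#' @keywords internal
test_spec <- function(test) {
  spec <- battery_specs()
  row <- spec[spec$test == test, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown test name: '", test, "'; battery tests are ",
         paste(spec$test, collapse = ", "), call. = FALSE)
  }
  row
}
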