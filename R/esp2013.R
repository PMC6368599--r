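#' European Standard Population 2013
#'
#' The 21 five-year age groups (0, 1-4, 5-9, ..., 90-94, 95+) of the 2013
#' European Standard Population with their standard weights, which sum to
#' 100,000. Used both for age standardization of incidence rates and as the
#' age strata for matching.
#'
#' @return data.frame with `group` (1-21), `label`, `age_low`, `age_high`
#'   (inclusive integer years; `Inf` for the open-ended last group) and
#'   `weight`.
#' @export
esp2013 <- function() {
  lows <- c(0, 1, seq(5, 95, by = 5))
  highs <- c(0, 4, seq(9, 94, by = 5), Inf)
  weights <- c(1000, 4000, 5500, 5500, 5500, 6000, 6000, 6500, 7000, 7000,
               7000, 7000, 6500, 6000, 5500, 5000, 4000, 2500, 1500, 800,
               200)
  data.frame(
    group = seq_len(21),
    label = c("0", "1-4", paste(seq(5, 90, 5), seq(9, 94, 5), sep = "-"),
              "95+"),
    age_low = lows, age_high = highs, weight = weights)
}

#' Age group assignment under the ESP2013 grouping
#'
#' @param age_years numeric ages (years, fractional allowed).
#' @return integer group index 1-21.
#' @export
esp_age_group <- function(age_years) {
  if (any(age_years < 0, na.rm = TRUE)) stop("negative age")
  brk <- c(0, 1, seq(5, 95, by = 5), Inf)
  findInterval(age_years, brk, rightmost.closed = FALSE)
}
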