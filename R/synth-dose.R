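#' Simulate a bead-uptake dose-response data set
#'
#' Generates replicate bead-pixels-per-cell values at the three nominal
#' exposure concentrations (7.81, 15.63, 31.25 µg/cm² by default) from a
#' linear truth with Gaussian noise, truncated at zero as uptake cannot be
#' negative.
#'
#' @param truth_slope True slope (bead px per cell per µg/cm²).
#' @param truth_intercept True intercept (bead px per cell).
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param n_replicates Replicates per concentration (>= 2).
#' @param concentrations Exposure concentrations in µg/cm².
#' @param cell_line,time_h Metadata attached to every record.
#' @param seed Integer seed (mandatory).
#' @return A tibble of class `dose_response_set` with columns `cell_line`,
#'   `concentration`, `time_h`, `replicate`, `bead_px_per_cell`; the planted
#'   truth is attached as attributes `truth_slope`, `truth_intercept`,
#'   `noise_sd`.
#' @examples
#' make_dose_response_set(2, 5, 1, n_replicates = 6, seed = 1)
#' @export
make_dose_response_set <- function(truth_slope, truth_intercept, noise_sd,
                                   n_replicates,
                                   concentrations = c(7.81, 15.63, 31.25),
                                   cell_line = "THP-1", time_h = 24,
                                   seed) {
  if (missing(seed)) abort("a seed is mandatory for fixture generation")
  if (n_replicates < 2) abort("n_replicates must be at least 2")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  withr::with_seed(seed, {
    df <- tidyr::expand_grid(concentration = concentrations,
                             replicate = seq_len(n_replicates))
    mu <- truth_intercept + truth_slope * df$concentration
    vals <- pmax(0, mu + stats::rnorm(nrow(df), sd = noise_sd))
    out <- tibble::tibble(
      cell_line = cell_line,
      concentration = df$concentration,
      time_h = time_h,
      replicate = df$replicate,
      bead_px_per_cell = vals
    )
    attr(out, "truth_slope") <- truth_slope
    attr(out, "truth_intercept") <- truth_intercept
    attr(out, "noise_sd") <- noise_sd
    class(out) <- c("dose_response_set", class(out))
    out
  })
}
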