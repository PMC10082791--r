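#' Generate a ground-truth cell population
#'
#' Draws a population of simulated cells with known functional identity, used
#' to drive the trace simulator and to benchmark every analysis stage against
#' ground truth. Classes:
#' \describe{
#'   \item{heading}{one light-invariant tuning peak.}
#'   \item{landmark}{two peaks 180 degrees apart, active only with lights on;
#'     baseline firing in darkness.}
#'   \item{alignment}{two peaks 180 degrees apart in light, collapsing to a
#'     single peak in darkness that coincides with one of the light-on peaks.}
#'   \item{untuned}{flat baseline firing.}
#' }
#' Default class proportions follow the emulated study population: 12.1% of
#' cells tuned, split 33% landmark / 28% alignment / 22% heading (the tuned
#' remainder is assigned to the heading class, the closest archetype for
#' other-tuned cells).
#'
#' @param n_cells number of cells.
#' @param class_mix named proportions over
#'   `c("heading","landmark","alignment","untuned")`; must be nonnegative and
#'   sum to 1. Counts are largest-remainder rounded.
#' @param peak_rate,baseline_rate,tuning_width_deg per-class response
#'   parameters (spikes/s and degrees); scalars or length-n vectors.
#' @param second_peak_ratio amplitude of the secondary (cue-symmetric) peak
#'   of landmark and alignment cells relative to the primary peak, in (0, 1]
#'   (default 0.7; real bimodal cells have unequal peaks, and exact symmetry
#'   is a degenerate case for decoding).
#' @param neuropil_alpha_range,calcium_gamma_range,noise_sd ranges/values for
#'   the fluorescence model (contamination fraction, AR(1) coefficient,
#'   additive noise SD in fluorescence a.u.).
#' @param preferred_deg optional vector of preferred directions; default
#'   uniform on the circle.
#' @param seed integer seed.
#' @return data frame of class `ground_truth_population` with one row per cell.
#' @export
generate_population <- function(n_cells,
                                class_mix = c(heading = 0.121 * 0.39,
                                              landmark = 0.121 * 0.33,
                                              alignment = 0.121 * 0.28,
                                              untuned = 0.879),
                                peak_rate = 10,
                                baseline_rate = 0.5,
                                tuning_width_deg = 35,
                                second_peak_ratio = 0.7,
                                neuropil_alpha_range = c(0.3, 0.7),
                                calcium_gamma_range = c(0.85, 0.95),
                                noise_sd = 0.05,
                                preferred_deg = NULL,
                                seed = 1L) {
  if (any(class_mix < 0)) stop("class proportions must be nonnegative")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class proportions must sum to 1")
  classes <- c("heading", "landmark", "alignment", "untuned")
  if (!all(names(class_mix) %in% classes)) stop("unknown class name in class_mix")
  mix <- stats::setNames(rep(0, 4), classes)
  mix[names(class_mix)] <- class_mix
  set.seed(seed)
  if (n_cells == 0L) {
    pop <- data.frame(cell_id = integer(0), class = character(0),
                      preferred_deg = numeric(0), dark_peak_deg = numeric(0),
                      peak_rate = numeric(0), baseline_rate = numeric(0),
                      tuning_width_deg = numeric(0), neuropil_alpha = numeric(0),
                      calcium_gamma = numeric(0), noise_sd = numeric(0))
    class(pop) <- c("ground_truth_population", "data.frame")
    return(pop)
  }
  # largest-remainder rounding of class counts
  raw <- mix * n_cells
  cnt <- floor(raw)
  rem <- n_cells - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  cls <- rep(classes, times = cnt)
  if (is.null(preferred_deg)) preferred_deg <- stats::runif(n_cells, 0, 360)
  # alignment cells keep one of their two light-on peaks in darkness
  dark_peak <- wrap360(preferred_deg + 180 * stats::rbinom(n_cells, 1, 0.5))
  pop <- data.frame(
    cell_id = seq_len(n_cells),
    class = cls,
    preferred_deg = wrap360(preferred_deg),
    dark_peak_deg = dark_peak,
    peak_rate = rep_len(peak_rate, n_cells),
    baseline_rate = rep_len(baseline_rate, n_cells),
    tuning_width_deg = rep_len(tuning_width_deg, n_cells),
    peak2_ratio = rep_len(second_peak_ratio, n_cells),
    neuropil_alpha = stats::runif(n_cells, neuropil_alpha_range[1],
                                  neuropil_alpha_range[2]),
    calcium_gamma = stats::runif(n_cells, calcium_gamma_range[1],
                                 calcium_gamma_range[2]),
    noise_sd = rep_len(noise_sd, n_cells))
  pop$peak_rate[pop$class == "untuned"] <- 0
  class(pop) <- c("ground_truth_population", "data.frame")
  pop
}

#' @export
print.ground_truth_population <- function(x, ...) {
  cat(sprintf("ground_truth_population: %d cells\n", nrow(x)))
  if (nrow(x)) print(table(factor(x$class,
    levels = c("heading", "landmark", "alignment", "untuned"))))
  invisible(x)
}

# circular-Gaussian bump, peak 1 at the preferred direction
gauss_bump <- function(theta, mu, width) exp(-(circ_diff(theta, mu) / width)^2)

#' Ground-truth firing rate of one cell at given headings
#'
#' Evaluates the generating rate map: baseline plus circular-Gaussian bumps
#' whose number and light dependence follow the cell's class.
#'
#' @param cell one row of a [generate_population()] data frame.
#' @param heading headings in degrees.
#' @param light_on logical, recycled to `length(heading)`.
#' @return firing rate in spikes/s per sample.
#' @export
cell_rate <- function(cell, heading, light_on = TRUE) {
  light_on <- rep_len(light_on, length(heading))
  b <- cell$baseline_rate; p <- cell$peak_rate; w <- cell$tuning_width_deg
  p2 <- if ("peak2_ratio" %in% names(cell)) cell$peak2_ratio else 1
  r <- rep(b, length(heading))
  if (cell$class == "heading") {
    r <- r + p * gauss_bump(heading, cell$preferred_deg, w)
  } else if (cell$class == "landmark") {
    bump <- p * (gauss_bump(heading, cell$preferred_deg, w) +
                 p2 * gauss_bump(heading, cell$preferred_deg + 180, w))
    r <- r + ifelse(light_on, bump, 0)
  } else if (cell$class == "alignment") {
    on_bump <- p * (gauss_bump(heading, cell$preferred_deg, w) +
                    p2 * gauss_bump(heading, cell$preferred_deg + 180, w))
    off_bump <- p * gauss_bump(heading, cell$dark_peak_deg, w)
    r <- r + ifelse(light_on, on_bump, off_bump)
  }
  r
}

#' Remap a population to a new visual context
#'
#' Rotates the preferred directions of all tuned cells by a common offset,
#' emulating coherent remapping when wall cues are replaced. A configurable
#' fraction of tuned cells instead receives independent uniform offsets
#' (incoherent remappers).
#'
#' @param pop a `ground_truth_population`.
#' @param offset_deg common rotation in [0, 360).
#' @param incoherent_fraction fraction of tuned cells remapping incoherently.
#' @param seed seed for the incoherent draws.
#' @return the remapped population (same shape, class labels untouched).
#' @export
apply_remap <- function(pop, offset_deg, incoherent_fraction = 0, seed = 1L) {
  stopifnot(offset_deg >= 0, offset_deg < 360,
            incoherent_fraction >= 0, incoherent_fraction <= 1)
  set.seed(seed)
  tuned <- which(pop$class != "untuned")
  off <- rep(offset_deg, length(tuned))
  n_inc <- round(incoherent_fraction * length(tuned))
  if (n_inc > 0) {
    pick <- sample(seq_along(tuned), n_inc)
    off[pick] <- stats::runif(n_inc, 0, 360)
  }
  pop$preferred_deg[tuned] <- wrap360(pop$preferred_deg[tuned] + off)
  pop$dark_peak_deg[tuned] <- wrap360(pop$dark_peak_deg[tuned] + off)
  pop
}
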