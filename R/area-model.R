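#' Soma-area model for preBotzinger complex neurons and glia
#'
#' Describes the two non-overlapping soma-area populations used throughout the
#' package: large neuronal somata (mean 389 um^2, sd 102) and small glial
#' somata (mean 88 um^2, sd 22). Both classes are modeled as truncated
#' normals: neurons are bounded below at `neuron_floor` and glia are bounded
#' to `[glia_floor, glia_ceiling]`, so that the two populations cannot
#' overlap and every area is positive. The truncation bounds straddle the
#' 200 um^2 classification threshold, so a correctly measured area is always
#' classified to its true population.
#'
#' Naive truncation of a normal shifts its mean (cutting the neuron
#' distribution at 210 um^2 raises the mean by ~9 um^2, a 2.3% bias). The
#' constructor therefore solves for the location parameter of each truncated
#' normal so that the *achieved* (post-truncation) mean equals the nominal
#' class mean. The achieved standard deviations are slightly smaller than the
#' nominal ones (neurons ~92 vs 102 um^2); the nominal sd is kept as the
#' scale parameter.
#'
#' @param neuron_mean,neuron_sd Target mean and scale of the neuron soma-area
#'   distribution, um^2.
#' @param glia_mean,glia_sd Target mean and scale of the glia soma-area
#'   distribution, um^2.
#' @param neuron_floor Lower truncation bound for neuron areas, um^2.
#' @param glia_ceiling Upper truncation bound for glia areas, um^2. Must be
#'   below `neuron_floor` so the populations cannot overlap.
#' @param glia_floor Lower truncation bound for glia areas, um^2 (a soma of
#'   30 um^2 has a diameter of about 6 um, a physical lower bound for
#'   astrocyte somata; it also guarantees positive areas).
#' @return An object of class `area_model`.
#' @examples
#' m <- area_model()
#' a <- generate_soma_areas(1000, 1000, m, seed = 1)
#' tapply(a$area_um2, a$true_class, mean)
#' @export
area_model <- function(neuron_mean = 389, neuron_sd = 102,
                       glia_mean = 88, glia_sd = 22,
                       neuron_floor = 210, glia_ceiling = 160,
                       glia_floor = 30) {
  for (nm in c("neuron_mean", "neuron_sd", "glia_mean", "glia_sd",
               "neuron_floor", "glia_ceiling", "glia_floor"))
    check_number(get(nm), nm, positive = TRUE)
  if (glia_ceiling >= neuron_floor)
    stop_arg("glia_ceiling (%g) must be < neuron_floor (%g): the class distributions must not overlap",
             glia_ceiling, neuron_floor)
  if (glia_floor >= glia_ceiling)
    stop_arg("glia_floor must be < glia_ceiling")
  if (glia_mean <= glia_floor || glia_mean >= glia_ceiling)
    stop_arg("glia_mean must lie strictly between glia_floor and glia_ceiling")
  if (neuron_mean <= neuron_floor)
    stop_arg("neuron_mean must exceed neuron_floor")

  m <- structure(
    list(neuron_mean = neuron_mean, neuron_sd = neuron_sd,
         glia_mean = glia_mean, glia_sd = glia_sd,
         neuron_floor = neuron_floor, glia_ceiling = glia_ceiling,
         glia_floor = glia_floor),
    class = "area_model")
  m$neuron_location <- match_truncnorm_location(neuron_mean, neuron_sd,
                                                neuron_floor, Inf)
  m$glia_location <- match_truncnorm_location(glia_mean, glia_sd,
                                              glia_floor, glia_ceiling)
  m
}

#' @export
print.area_model <- function(x, ...) {
  cat("Soma-area model (um^2)\n")
  cat(sprintf("  neurons: mean %g, sd %g, truncated to [%g, Inf)\n",
              x$neuron_mean, x$neuron_sd, x$neuron_floor))
  cat(sprintf("  glia:    mean %g, sd %g, truncated to [%g, %g]\n",
              x$glia_mean, x$glia_sd, x$glia_floor, x$glia_ceiling))
  invisible(x)
}

# Mean of N(mu, sd) truncated to [lower, upper].
truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  mu + sd * (dnorm(a) - dnorm(b)) / Z
}

# Location parameter mu such that the [lower, upper]-truncated N(mu, sd) has
# the requested mean.
match_truncnorm_location <- function(target_mean, sd, lower, upper) {
  f <- function(mu) truncnorm_mean(mu, sd, lower, upper) - target_mean
  uniroot(f, interval = target_mean + c(-4, 4) * sd, tol = 1e-10)$root
}

# Exact inverse-CDF sampler for the truncated normal (no rejection loop).
rtruncnorm <- function(n, mu, sd, lower, upper) {
  if (n == 0L) return(numeric(0))
  plo <- pnorm((lower - mu) / sd)
  phi <- pnorm((upper - mu) / sd)
  mu + sd * qnorm(runif(n, plo, phi))
}

#' Draw soma areas for a mix of neurons and glia
#'
#' Samples `n_neurons` neuron soma areas and `n_glia` glia soma areas from the
#' truncated-normal populations of an [area_model()]. By construction no glia
#' area can exceed any neuron area.
#'
#' @param n_neurons,n_glia Number of areas to draw per class (>= 0).
#' @param model An [area_model()].
#' @param seed Integer seed; identical seeds give identical draws.
#' @return A data frame with columns `area_um2` and `true_class`
#'   (`"neuron"`/`"glia"`), neurons first.
#' @export
generate_soma_areas <- function(n_neurons, n_glia, model = area_model(),
                                seed = NULL) {
  check_number(n_neurons, "n_neurons", nonneg = TRUE)
  check_number(n_glia, "n_glia", nonneg = TRUE)
  if (!inherits(model, "area_model")) stop_arg("`model` must be an area_model")
  n_neurons <- as.integer(n_neurons); n_glia <- as.integer(n_glia)
  with_seed_or_current(seed, {
    neu <- rtruncnorm(n_neurons, model$neuron_location, model$neuron_sd,
                      model$neuron_floor, Inf)
    gli <- rtruncnorm(n_glia, model$glia_location, model$glia_sd,
                      model$glia_floor, model$glia_ceiling)
    data.frame(
      area_um2 = c(neu, gli),
      true_class = rep(c("neuron", "glia"), c(n_neurons, n_glia)),
      stringsAsFactors = FALSE)
  })
}
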