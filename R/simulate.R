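#' Succession parameters for the synthetic community generator
#'
#' Describes a fermentation time course: each taxon follows a latent
#' trajectory over stages (logistic rise or fall, a transient Gaussian
#' bloom, or a stable level), scaled by a taxon-specific carrying weight.
#' Replicate count vectors are drawn Dirichlet-multinomial around the
#' stage composition, so replicates are overdispersed relative to plain
#' multinomial resampling.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param n_stages Number of fermentation stages (default 6, labelled
#'   A, B, C, ...).
#' @param n_replicates Replicates per stage (default 3).
#' @param profiles Optional tibble with columns `taxon`, `kind`
#'   (`rising`, `falling`, `transient`, `stable`), `midpoint`, `rate`,
#'   `weight` and optionally `floor` (resting intensity relative to the
#'   trajectory peak). Randomized from `seed` when `NULL`.
#' @param depth Sequencing depth: every sample's counts sum to this.
#' @param concentration Dirichlet concentration (total mass) controlling
#'   replicate overdispersion; larger is tighter. Values `>= 1e12` (or
#'   `Inf`) switch off both the Dirichlet and the multinomial draw and
#'   return deterministically rounded counts (the noiseless limit).
#' @param stage_noise_sd Lognormal sigma of per-(taxon, stage) biological
#'   fluctuation around the smooth trajectory, shared by the replicates
#'   of a stage. Real genera do not follow clean logistic curves; this
#'   irregular component (default 0.4) is what distinguishes one taxon's
#'   realized series from another's. Set to 0 for perfectly smooth
#'   trajectories.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list of class `succession_params`.
#' @export
succession_params <- function(n_taxa, n_stages = 6, n_replicates = 3,
                              profiles = NULL, depth = 1e4,
                              concentration = 30, stage_noise_sd = 0.4,
                              seed = 1) {
  stopifnot(n_taxa >= 2, n_stages >= 2, n_replicates >= 1,
            depth > 0, concentration > 0, stage_noise_sd >= 0)
  if (is.null(profiles)) {
    profiles <- withr::with_seed(seed, random_profiles(n_taxa))
  }
  bad <- setdiff(profiles$kind, c("rising", "falling", "transient", "stable"))
  if (length(bad)) stop("unknown trajectory kind: ", bad[1], call. = FALSE)
  structure(list(n_taxa = n_taxa, n_stages = n_stages,
                 n_replicates = n_replicates, profiles = profiles,
                 depth = depth, concentration = concentration,
                 stage_noise_sd = stage_noise_sd, seed = seed),
            class = "succession_params")
}

random_profiles <- function(n_taxa,
                            taxa = sprintf("Taxon%02d", seq_len(n_taxa)),
                            weight_sd = 1) {
  tibble::tibble(
    taxon = taxa,
    kind = sample(c("rising", "falling", "transient", "stable"),
                  n_taxa, replace = TRUE),
    midpoint = stats::runif(n_taxa, 0.1, 0.9),
    rate = stats::runif(n_taxa, 3, 15),
    weight = exp(stats::rnorm(n_taxa, 0, weight_sd)),
    floor = stats::runif(n_taxa, 0.2, 0.6))
}

# Latent stage intensity of one taxon at scaled times s in [0, 1].
# `floor` is the resting intensity relative to the trajectory peak; it
# sets the dynamic range of the smooth component.
trajectory <- function(kind, s, midpoint, rate, floor = 0.05) {
  amp <- 1 - floor
  switch(kind,
         rising = floor + amp / (1 + exp(-rate * (s - midpoint))),
         falling = floor + amp / (1 + exp(rate * (s - midpoint))),
         transient = floor + amp * exp(-((s - midpoint) / 0.18)^2),
         stable = rep(1, length(s)),
         stop("unknown trajectory kind: ", kind, call. = FALSE))
}

#' Simulate a succession count table
#'
#' @param p A [succession_params] object.
#' @return An [abund_tbl] in counts mode, `n_stages * n_replicates`
#'   samples by `n_taxa` taxa.
#' @export
generate_succession <- function(p) {
  stopifnot(inherits(p, "succession_params"))
  s <- seq(0, 1, length.out = p$n_stages)
  lat <- vapply(seq_len(nrow(p$profiles)), function(j) {
    pr <- p$profiles[j, ]
    fl <- if ("floor" %in% names(pr)) pr$floor else 0.05
    pr$weight * trajectory(pr$kind, s, pr$midpoint, pr$rate, floor = fl)
  }, numeric(p$n_stages))                       # stages x taxa
  stages <- LETTERS[seq_len(p$n_stages)]
  noiseless <- is.infinite(p$concentration) || p$concentration >= 1e12

  rows <- withr::with_seed(p$seed, {
    if (!noiseless && p$stage_noise_sd > 0) {
      lat <- lat * exp(matrix(stats::rnorm(length(lat), 0, p$stage_noise_sd),
                              nrow(lat)))
    }
    prob <- lat / rowSums(lat)
    purrr::map_dfr(seq_len(p$n_stages), function(i) {
      purrr::map_dfr(seq_len(p$n_replicates), function(r) {
        if (noiseless) {
          cnt <- round(p$depth * prob[i, ])
        } else {
          alpha <- p$concentration * prob[i, ]
          g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
          # all-zero gamma draw is theoretically possible for tiny alpha
          if (sum(g) <= 0) g <- prob[i, ]
          cnt <- as.numeric(stats::rmultinom(1, p$depth, g / sum(g)))
        }
        names(cnt) <- p$profiles$taxon
        dplyr::bind_cols(tibble::tibble(stage = stages[i], replicate = r),
                         tibble::as_tibble(as.list(cnt)))
      })
    })
  })
  abund_tbl(rows, kingdom = "synthetic", mode = "counts")
}

#' Ground-truth microbe-to-volatile association structure
#'
#' Encodes the planted model: log-concentration of compound k in sample i
#' is `baseline_k + sum_j B[j, k] * relabund[i, j] + eps`,
#' `eps ~ N(0, noise_sd^2)`.
#'
#' @param B Taxa-by-compounds effect matrix with dimnames.
#' @param baseline Per-compound baseline log-concentration (recycled).
#' @param noise_sd Lognormal measurement noise sigma (log scale).
#' @return A list of class `association_truth` with the derived
#'   `core_taxa` / `core_compounds` sets (rows/columns of `B` with any
#'   nonzero entry).
#' @export
association_truth <- function(B, baseline = 0, noise_sd = 0.05) {
  stopifnot(is.matrix(B), !is.null(rownames(B)), !is.null(colnames(B)),
            noise_sd >= 0)
  baseline <- rep_len(baseline, ncol(B))
  names(baseline) <- colnames(B)
  structure(list(B = B, baseline = baseline, noise_sd = noise_sd,
                 core_taxa = rownames(B)[rowSums(B != 0) > 0],
                 core_compounds = colnames(B)[colSums(B != 0) > 0]),
            class = "association_truth")
}

#' @rdname association_truth
#' @param truth An `association_truth`.
#' @return `truth_report()`: list with `core_taxa` and `core_compounds`.
#' @export
truth_report <- function(truth) {
  stopifnot(inherits(truth, "association_truth"))
  list(core_taxa = truth$core_taxa, core_compounds = truth$core_compounds)
}

#' Simulate volatile concentrations from an abundance table
#'
#' @param abund An [abund_tbl] (counts are converted to relative
#'   abundances internally).
#' @param truth An [association_truth]; `rownames(truth$B)` must equal
#'   the taxa of `abund` and `colnames(truth$B)` name the compounds.
#' @param seed Integer seed for the measurement noise.
#' @param response `"log"` (default, concentrations are exponentials of
#'   the linear predictor) or `"linear"` (the predictor itself, floored
#'   at zero) for worst-case testing of downstream linearity assumptions.
#' @return A [volatile_tbl] with one row per sample and compound
#'   (`class = "synthetic"`).
#' @export
generate_volatiles <- function(abund, truth, seed = 1,
                               response = c("log", "linear")) {
  response <- match.arg(response)
  stopifnot(inherits(truth, "association_truth"))
  rel <- abund_matrix(to_relative(abund))
  if (!identical(colnames(rel), rownames(truth$B))) {
    if (!setequal(colnames(rel), rownames(truth$B))) {
      stop("B rows do not match the taxa of the abundance table",
           call. = FALSE)
    }
    rel <- rel[, rownames(truth$B), drop = FALSE]
  }
  eta <- sweep(rel %*% truth$B, 2, truth$baseline, "+")
  eps <- withr::with_seed(seed,
    matrix(stats::rnorm(length(eta), 0, truth$noise_sd), nrow(eta)))
  conc <- if (response == "log") exp(eta + eps) else pmax(eta + eps, 0)
  out <- tibble::as_tibble(conc)
  out$stage <- abund$stage
  out$replicate <- abund$replicate
  long <- tidyr::pivot_longer(out, cols = -c("stage", "replicate"),
                              names_to = "compound",
                              values_to = "concentration")
  long$class <- "synthetic"
  volatile_tbl(long)
}

#' Simulate a complete fermentation study with planted associations
#'
#' Study-design defaults mirror a six-stage, triplicate spontaneous
#' fermentation: 40 genera at sequencing depth 10^4 with 5 planted
#' "core" taxa, each driving one volatile compound log-linearly with
#' effect size `effect` (alternating sign) against lognormal measurement
#' noise; compounds beyond the first `n_core` are baseline noise. Core
#' taxa are assigned dynamic trajectories (rising, falling, transient in
#' rotation), as dominant fermentative genera show in practice; all taxa
#' carry randomized trajectory shapes, irregular per-stage fluctuation
#' and replicate-level Dirichlet overdispersion, the variance structure
#' genus-level community series show in real fermentations (see the
#' methods vignette for why this matters for identifiability).
#'
#' @param n_taxa,n_stages,n_replicates,depth,concentration,stage_noise_sd
#'   See [succession_params()].
#' @param n_core Number of planted core taxa (`n_compounds >= n_core`).
#' @param n_compounds Number of volatile compounds.
#' @param effect Absolute log-linear effect size of planted associations.
#' @param noise_sd Measurement noise sigma on the log scale.
#' @param seed Integer seed driving the whole simulation.
#' @return List with `abund` ([abund_tbl], counts), `volatiles`
#'   ([volatile_tbl]) and `truth` ([association_truth]).
#' @export
simulate_ferment_study <- function(n_taxa = 40, n_core = 5, n_stages = 6,
                                   n_replicates = 3, n_compounds = 5,
                                   effect = 3, noise_sd = 0.05,
                                   depth = 1e4, concentration = 30,
                                   stage_noise_sd = 0.4, seed = 1) {
  stopifnot(n_core < n_taxa, n_compounds >= n_core)
  taxa <- sprintf("Taxon%02d", seq_len(n_taxa))
  compounds <- sprintf("Compound%02d", seq_len(n_compounds))

  setup <- withr::with_seed(seed, {
    prof <- random_profiles(n_taxa, taxa, weight_sd = 0.3)
    core <- sort(sample(n_taxa, max(n_core, 1)))[seq_len(n_core)]
    if (n_core > 0) {
      prof$kind[core] <- rep(c("rising", "falling", "transient"),
                             length.out = n_core)
    }
    list(prof = prof, core = core)
  })
  B <- matrix(0, n_taxa, n_compounds, dimnames = list(taxa, compounds))
  if (n_core > 0) {
    for (i in seq_len(n_core)) {
      B[setup$core[i], i] <- effect * (-1)^(i + 1)
    }
  }
  truth <- association_truth(B, baseline = log(100), noise_sd = noise_sd)
  p <- succession_params(n_taxa, n_stages, n_replicates,
                         profiles = setup$prof, depth = depth,
                         concentration = concentration,
                         stage_noise_sd = stage_noise_sd, seed = seed)
  abund <- generate_succession(p)
  volatiles <- generate_volatiles(abund, truth, seed = seed + 1L)
  list(abund = abund, volatiles = volatiles, truth = truth)
}
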