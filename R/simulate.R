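#' Simulation configuration for synthetic sepsis cohorts
#'
#' Describes a cohort generatively: per-group latent panel means on the
#' log2(CPM+1) score scale, between-sample spread, an optional mixture
#' component for the bidirectional interferon panels, an optional linear
#' SOFA model tied to the latent NDrG score, and (for longitudinal
#' designs) per-time-point mean changes. [simulate_cohort()] and
#' [simulate_longitudinal()] turn a configuration into raw negative-
#' binomial counts plus metadata, so configured score-scale effects are
#' recovered only after the full normalize-and-score round trip.
#'
#' @param groups A list of group specifications. Each is a list with
#'   elements `group` (label), `n` (samples or subjects), `mu` (named
#'   numeric vector of latent panel means, one per panel), and optionally
#'   `outcome` (`"survivor"`, `"non-survivor"` or `"unknown"`, default
#'   unknown), `mixture` (named list: per panel a list with `shifts` and
#'   `probs` describing a discrete mixture of latent-mean shifts),
#'   `sofa` (list with `intercept`, `slope`, `sd`: SOFA is
#'   `clip(round(intercept + slope * L_NDrG + N(0, sd^2)), 0, 24)`; groups
#'   without a model get missing SOFA), `sex_split` (fraction of female
#'   samples; default unknown sex), and for longitudinal designs `deltas`
#'   (panels x transitions numeric matrix of latent mean changes between
#'   consecutive time points).
#' @param panels Panel definition tibble; defaults to [builtin_panels()].
#' @param timepoints Character vector of ordered time-point labels for
#'   longitudinal designs, or `NULL` for cross-sectional cohorts.
#' @param delta_sd Between-subject SD of each per-time-point latent change
#'   (log2 units).
#' @param sigma Between-sample SD of the latent panel scores (scalar or
#'   named per-panel vector, log2 units).
#' @param tau Within-panel gene-level noise SD around the latent score
#'   (log2 units).
#' @param phi Negative-binomial dispersion of the counts; `0` means
#'   deterministic counts (the rounded expected count), used for noiseless
#'   round-trip checks.
#' @param n_background Number of background genes outside the panels.
#' @param background_range Range of background gene log2(CPM+1) means.
#' @param libsize_range Range of per-sample library sizes (total counts).
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(groups,
                       panels = builtin_panels(),
                       timepoints = NULL,
                       delta_sd = 0.3,
                       sigma = 1.0,
                       tau = 0.5,
                       phi = 0.1,
                       n_background = 2000,
                       background_range = c(1, 9),
                       libsize_range = c(5e6, 2e7)) {
  pnames <- unique(panels$panel)
  if (is.null(names(sigma))) {
    sigma <- stats::setNames(rep(sigma[1], length(pnames)), pnames)
  }
  cfg <- structure(
    list(groups = groups, panels = panels, timepoints = timepoints,
         delta_sd = delta_sd, sigma = sigma, tau = tau, phi = phi,
         n_background = n_background, background_range = background_range,
         libsize_range = libsize_range),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pnames <- unique(cfg$panels$panel)
  stopifnot(length(cfg$groups) >= 1)
  for (g in cfg$groups) {
    if (is.null(g$group) || is.null(g$n) || is.null(g$mu)) {
      stop("each group spec needs 'group', 'n' and 'mu'", call. = FALSE)
    }
    if (g$n < 1) stop("group '", g$group, "': n must be >= 1", call. = FALSE)
    if (!all(pnames %in% names(g$mu))) {
      stop("group '", g$group, "': mu must name every panel", call. = FALSE)
    }
    if (!is.null(g$deltas)) {
      if (!is.matrix(g$deltas) || !all(pnames %in% rownames(g$deltas))) {
        stop("group '", g$group,
             "': deltas must be a panels x transitions matrix", call. = FALSE)
      }
    }
  }
  if (any(cfg$sigma < 0) || cfg$tau < 0 || cfg$phi < 0 || cfg$delta_sd < 0) {
    stop("sigma, tau, phi and delta_sd must be non-negative", call. = FALSE)
  }
  if (any(cfg$libsize_range <= 0)) {
    stop("library sizes must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Named cohort presets mirroring the published study designs
#'
#' Each preset reproduces the group sizes of one published cohort and sets
#' the latent panel mean offsets between groups (or between time points)
#' to the published mean differences for the unidirectional panels NDrG,
#' HLAd and LYMd. The bidirectional interferon panels (ISGa, GBPs) are
#' configured as discrete mixtures of shifted and unshifted samples where
#' the source cohort reported both directions. Absolute expression levels,
#' within-group spreads and the noise chain are the package's own
#' plausible bulk RNA-seq choices (see the methods vignette).
#'
#' Available presets:
#' \describe{
#'   \item{sepsis_vs_control}{14 sepsis vs 15 healthy controls; NDrG/HLAd/
#'     LYMd offsets +5.0 / -1.75 / -2.18; GBPs suppressed in 10 of 14
#'     sepsis samples.}
#'   \item{hyper_vs_hypo}{76 hyper- vs 113 hypo-inflammation patients,
#'     with sex labels.}
#'   \item{surgery_crp}{21 high-CRP vs 25 low-CRP surgery patients at two
#'     time points.}
#'   \item{shock_timecourse}{21 septic-shock subjects at three ICU time
#'     points; total NDrG/HLAd/LYMd change -1.70 / +1.06 / +1.08.}
#'   \item{responders_48h}{17 responders vs 14 non-responders at ICU
#'     admission and 48 h.}
#'   \item{responders_day8}{23 responders vs 14 non-responders at day 1
#'     and day 8.}
#'   \item{icu_outcome}{60 survivors, 18 non-survivors, 44 healthy
#'     controls; survivor-minus-non-survivor offsets -1.71 / +1.39 /
#'     +0.92 and a SOFA model calibrated to r = 0.508 with NDrG.}
#' }
#'
#' @param name Preset name (see above).
#' @return A [sim_config()] object.
#' @examples
#' preset("sepsis_vs_control")
#' @export
preset <- function(name) {
  presets <- c("sepsis_vs_control", "hyper_vs_hypo", "surgery_crp",
               "shock_timecourse", "responders_48h", "responders_day8",
               "icu_outcome")
  if (!is.character(name) || length(name) != 1L || !name %in% presets) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(presets, collapse = ", "),
         call. = FALSE)
  }
  # latent panel means in healthy peripheral blood (log2 CPM+1 units)
  healthy <- c(NDrG = 5.0, ISGa = 6.0, GBPs = 7.0, HLAd = 9.0, LYMd = 7.0)
  mu <- function(...) {
    ov <- c(...)
    m <- healthy
    m[names(ov)] <- ov
    m
  }
  both_dirs <- list(shifts = c(-1.5, 0, 1.5), probs = c(0.3, 0.4, 0.3))

  switch(name,
    sepsis_vs_control = sim_config(list(
      list(group = "control", n = 15, mu = healthy),
      list(group = "sepsis", n = 14,
           mu = mu(NDrG = 10.0, HLAd = 7.25, LYMd = 4.82),
           mixture = list(GBPs = list(shifts = c(-1.5, 0),
                                      probs = c(10 / 14, 4 / 14))))
    )),
    hyper_vs_hypo = sim_config(list(
      list(group = "hypo", n = 113, sex_split = 0.5,
           mu = mu(NDrG = 9.0, HLAd = 7.6, LYMd = 5.6, GBPs = 6.5)),
      list(group = "hyper", n = 76, sex_split = 0.5,
           mu = mu(NDrG = 10.5, HLAd = 6.6, LYMd = 4.6, GBPs = 6.0))
    )),
    surgery_crp = sim_config(list(
      list(group = "high_crp", n = 21,
           mu = mu(NDrG = 6.0, HLAd = 8.8, LYMd = 6.8),
           deltas = delta_matrix(NDrG = 1.5, GBPs = -0.8,
                                 HLAd = -0.8, LYMd = -1.5)),
      list(group = "low_crp", n = 25,
           mu = mu(NDrG = 6.0, HLAd = 8.8, LYMd = 6.8),
           deltas = delta_matrix(NDrG = 0.5, GBPs = -0.2,
                                 HLAd = -0.2, LYMd = -0.5))
    ), timepoints = c("T0", "T1")),
    shock_timecourse = sim_config(list(
      list(group = "septic_shock", n = 21,
           mu = mu(NDrG = 10.0, ISGa = 6.5, GBPs = 6.5,
                   HLAd = 7.3, LYMd = 5.0),
           deltas = delta_matrix(NDrG = -0.85, HLAd = 0.53, LYMd = 0.54,
                                 transitions = 2))
    ), timepoints = c("T1", "T2", "T3")),
    responders_48h = sim_config(list(
      list(group = "responder", n = 17,
           mu = mu(NDrG = 9.61, ISGa = 6.5, GBPs = 6.5,
                   HLAd = 7.59, LYMd = 5.29),
           deltas = delta_matrix(NDrG = -1.04, HLAd = 0.63, LYMd = 0.64,
                                 GBPs = 0.77)),
      list(group = "non_responder", n = 14,
           mu = mu(NDrG = 10.2, ISGa = 6.5, GBPs = 6.5,
                   HLAd = 7.0, LYMd = 5.0),
           deltas = delta_matrix(NDrG = -1.08, HLAd = 0.80, LYMd = 0.28))
    ), timepoints = c("T1", "T2")),
    responders_day8 = sim_config(list(
      list(group = "responder", n = 23,
           mu = mu(NDrG = 9.36, ISGa = 6.5, GBPs = 6.5,
                   HLAd = 7.63, LYMd = 5.45),
           deltas = delta_matrix(NDrG = -1.26, ISGa = 0.8,
                                 HLAd = 0.71, LYMd = 0.78)),
      list(group = "non_responder", n = 14,
           mu = mu(NDrG = 10.2, ISGa = 6.5, GBPs = 6.5,
                   HLAd = 7.0, LYMd = 5.0),
           deltas = delta_matrix(NDrG = -1.06, ISGa = 0.8,
                                 HLAd = 0.58, LYMd = 0.56))
    ), timepoints = c("day1", "day8")),
    icu_outcome = {
      surv_mu <- mu(NDrG = 8.60, HLAd = 8.20, LYMd = 6.00)
      nonsurv_mu <- mu(NDrG = 10.31, HLAd = 6.81, LYMd = 5.08, GBPs = 5.70)
      sofa <- calibrate_sofa(mus = c(surv_mu[["NDrG"]], nonsurv_mu[["NDrG"]]),
                             n = c(60, 18), sigma = 1.0,
                             r_target = 0.508, slope = 2,
                             mean_sofa = 9)
      sim_config(list(
        list(group = "healthy", n = 44, mu = healthy,
             mixture = list(ISGa = both_dirs)),
        list(group = "survivor", n = 60, outcome = "survivor",
             mu = surv_mu, sofa = sofa,
             mixture = list(ISGa = both_dirs, GBPs = both_dirs)),
        list(group = "non-survivor", n = 18, outcome = "non-survivor",
             mu = nonsurv_mu, sofa = sofa,
             mixture = list(ISGa = both_dirs))
      ))
    }
  )
}

#' Build a per-panel delta matrix for longitudinal group specs
#'
#' @param ... Named per-transition changes for individual panels; panels
#'   not named get 0. Values are recycled across transitions.
#' @param transitions Number of consecutive time-point transitions.
#' @return A panels x transitions numeric matrix.
#' @export
delta_matrix <- function(..., transitions = 1) {
  pnames <- panel_order()
  ov <- c(...)
  m <- matrix(0, nrow = length(pnames), ncol = transitions,
              dimnames = list(pnames, NULL))
  for (p in names(ov)) m[p, ] <- ov[[p]]
  m
}

# Solve the SOFA-model noise SD so that cor(L_NDrG, SOFA) hits r_target
# under the configured group mixture (linear model; rounding and clipping
# attenuate r only marginally at these magnitudes).
calibrate_sofa <- function(mus, n, sigma, r_target, slope, mean_sofa) {
  w <- n / sum(n)
  mbar <- sum(w * mus)
  var_l <- sigma^2 + sum(w * (mus - mbar)^2)
  sd_noise <- slope * sqrt(var_l) * sqrt(1 / r_target^2 - 1)
  list(intercept = mean_sofa - slope * mbar, slope = slope, sd = sd_noise)
}

# Fixed within-panel gene offsets (sum to zero) so panel genes sit at
# distinct but score-neutral levels.
gene_offsets <- function(n) {
  if (n == 1) return(0)
  seq(-0.6, 0.6, length.out = n)
}

draw_latent <- function(g, n, cfg) {
  pnames <- unique(cfg$panels$panel)
  L <- matrix(0, nrow = n, ncol = length(pnames),
              dimnames = list(NULL, pnames))
  for (p in pnames) {
    L[, p] <- stats::rnorm(n, mean = g$mu[[p]], sd = cfg$sigma[[p]])
    mix <- g$mixture[[p]]
    if (!is.null(mix)) {
      shift <- sample(mix$shifts, n, replace = TRUE, prob = mix$probs)
      L[, p] <- L[, p] + shift
    }
  }
  L
}

draw_sofa <- function(g, l_ndrg) {
  if (is.null(g$sofa)) return(rep(NA_integer_, length(l_ndrg)))
  raw <- g$sofa$intercept + g$sofa$slope * l_ndrg +
    stats::rnorm(length(l_ndrg), sd = g$sofa$sd)
  as.integer(pmin(pmax(round(raw), 0), 24))
}

draw_sex <- function(g, n) {
  if (is.null(g$sex_split)) return(rep("unknown", n))
  nf <- round(g$sex_split * n)
  sample(c(rep("F", nf), rep("M", n - nf)))
}

# Convert latent panel scores (samples x panels) into a raw count matrix.
# Gene targets are latent score + fixed offset + N(0, tau^2); background
# genes fill the library so per-sample CPMs total 1e6, making the
# configured score-scale effects survive CPM renormalization.
counts_from_latent <- function(L, cfg) {
  n <- nrow(L)
  panels <- cfg$panels
  pnames <- unique(panels$panel)
  beta <- unlist(lapply(pnames, function(p) {
    gene_offsets(sum(panels$panel == p))
  }))
  panel_of_gene <- panels$panel

  target_panel <- t(L[, panel_of_gene, drop = FALSE]) + beta
  target_panel <- target_panel +
    matrix(stats::rnorm(length(target_panel), sd = cfg$tau),
           nrow = nrow(target_panel))
  rownames(target_panel) <- panels$gene

  bg_mu <- stats::runif(cfg$n_background,
                        cfg$background_range[1], cfg$background_range[2])
  target_bg <- matrix(bg_mu, nrow = cfg$n_background, ncol = n) +
    matrix(stats::rnorm(cfg$n_background * n, sd = cfg$tau),
           nrow = cfg$n_background)
  rownames(target_bg) <- sprintf("BG%04d", seq_len(cfg$n_background))

  cpm_panel <- pmax(2^pmax(target_panel, 0) - 1, 0)
  cpm_bg <- pmax(2^pmax(target_bg, 0) - 1, 0)
  panel_tot <- colSums(cpm_panel)
  if (any(panel_tot >= 1e6)) {
    stop("panel genes exceed the library; lower the configured means",
         call. = FALSE)
  }
  cpm_bg <- sweep(cpm_bg, 2, (1e6 - panel_tot) / colSums(cpm_bg), "*")
  cpm <- rbind(cpm_panel, cpm_bg)

  libsize <- stats::runif(n, cfg$libsize_range[1], cfg$libsize_range[2])
  mu_count <- sweep(cpm, 2, libsize / 1e6, "*")
  counts <- if (cfg$phi > 0) {
    matrix(stats::rnbinom(length(mu_count), mu = mu_count, size = 1 / cfg$phi),
           nrow = nrow(mu_count))
  } else {
    round(mu_count)
  }
  dimnames(counts) <- dimnames(cpm)
  counts
}

#' Simulate a cross-sectional cohort
#'
#' Draws, for every sample, a latent score per panel from its group's
#' configured distribution, expands the latent scores into per-gene
#' log2(CPM+1) targets, and generates negative-binomial raw counts at a
#' random library size. SOFA scores and outcome labels follow the group
#' specifications. The same seed always reproduces the same cohort.
#'
#' @param config A [sim_config()] (cross-sectional; any `deltas` are
#'   ignored here).
#' @param seed Integer seed driving all randomness of the draw.
#' @return A list with `expression` (an [expression_matrix()] of raw
#'   counts) and `metadata` (a sample tibble as from [read_metadata()]).
#' @examples
#' cohort <- simulate_cohort(preset("sepsis_vs_control"), seed = 1)
#' dim(cohort$expression)
#' @export
simulate_cohort <- function(config, seed) {
  validate_sim_config(config)
  withr::with_seed(as.integer(seed), {
    plans <- lapply(config$groups, function(g) {
      ids <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]+", "_", g$group),
                     seq_len(g$n))
      L <- draw_latent(g, g$n, config)
      meta <- tibble::tibble(
        sample_id = ids, subject_id = ids,
        group = g$group, timepoint = NA_character_,
        sex = draw_sex(g, g$n),
        sofa = draw_sofa(g, L[, "NDrG"]),
        outcome = if (is.null(g$outcome)) "unknown" else g$outcome
      )
      list(meta = meta, L = L)
    })
    meta <- dplyr::bind_rows(lapply(plans, `[[`, "meta"))
    L <- do.call(rbind, lapply(plans, `[[`, "L"))
    counts <- counts_from_latent(L, config)
    colnames(counts) <- meta$sample_id
    list(expression = expression_matrix(counts, scale = "raw_counts"),
         metadata = as_sample_records(meta))
  })
}

#' Simulate a paired longitudinal cohort
#'
#' Per subject, baseline latent panel scores are drawn as in
#' [simulate_cohort()]; each subsequent time point adds the group's
#' configured per-panel mean change plus subject-level noise
#' (`delta_sd`). All of a subject's samples share a `subject_id`, and
#' `timepoint` carries the ordered labels from the configuration.
#'
#' @param config A [sim_config()] with `timepoints` and per-group `deltas`.
#' @param seed Integer seed.
#' @return A list with `expression` (raw counts) and `metadata`.
#' @examples
#' cohort <- simulate_longitudinal(preset("shock_timecourse"), seed = 1)
#' table(cohort$metadata$timepoint)
#' @export
simulate_longitudinal <- function(config, seed) {
  validate_sim_config(config)
  tps <- config$timepoints
  if (is.null(tps) || length(tps) < 2) {
    stop("longitudinal simulation needs >= 2 configured timepoints",
         call. = FALSE)
  }
  if (any(vapply(config$groups, function(g) is.null(g$deltas), logical(1)))) {
    stop("every group needs a 'deltas' matrix for longitudinal simulation",
         call. = FALSE)
  }
  pnames <- unique(config$panels$panel)
  withr::with_seed(as.integer(seed), {
    plans <- lapply(config$groups, function(g) {
      subj <- sprintf("%s_s%03d", gsub("[^A-Za-z0-9]+", "_", g$group),
                      seq_len(g$n))
      L0 <- draw_latent(g, g$n, config)
      Ls <- vector("list", length(tps))
      Ls[[1]] <- L0
      for (t in seq_along(tps)[-1]) {
        step <- matrix(g$deltas[pnames, t - 1], nrow = g$n, ncol = length(pnames),
                       byrow = TRUE) +
          matrix(stats::rnorm(g$n * length(pnames), sd = config$delta_sd),
                 nrow = g$n)
        Ls[[t]] <- Ls[[t - 1]] + step
      }
      sex <- draw_sex(g, g$n)
      meta <- dplyr::bind_rows(lapply(seq_along(tps), function(t) {
        tibble::tibble(
          sample_id = paste0(subj, "_", tps[t]), subject_id = subj,
          group = g$group, timepoint = tps[t],
          sex = sex,
          sofa = draw_sofa(g, Ls[[t]][, "NDrG"]),
          outcome = if (is.null(g$outcome)) "unknown" else g$outcome
        )
      }))
      list(meta = meta, L = do.call(rbind, Ls))
    })
    meta <- dplyr::bind_rows(lapply(plans, `[[`, "meta"))
    L <- do.call(rbind, lapply(plans, `[[`, "L"))
    counts <- counts_from_latent(L, config)
    colnames(counts) <- meta$sample_id
    list(expression = expression_matrix(counts, scale = "raw_counts"),
         metadata = as_sample_records(meta))
  })
}
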