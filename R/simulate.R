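#' Simulation configuration for the synthetic study
#'
#' Encodes the emulated design: three age groups (defaults 7 young-adult
#' reference "6m", 7 "24m", 8 "28m"), negative-binomial counts with an
#' age-dependent differentially expressed fraction that is much larger at
#' 28m than 24m, two sequencing runs sharing re-prepared reference
#' libraries, and a latent per-animal physical-function value that
#' declines with age and is linearly coupled (on the log2 scale) to a
#' subset of the 28m DE genes.
#'
#' @param n_per_group named integer vector of animals per age group; the
#'   first group is the reference.
#' @param n_genes number of genes.
#' @param frac_de_24m,frac_de_28m fraction of genes differentially
#'   expressed in each old-vs-reference contrast (defaults 0.01, 0.08).
#' @param log2fc_mean,log2fc_sd mean and sd of |true log2fc| for DE genes.
#' @param dispersion_a0,dispersion_a1 parameters of the dispersion trend
#'   `alpha(mu) = a0 + a1/mu` (per-gene, at the gene's baseline mean).
#' @param libsize_sigma lognormal sd of library-size factors.
#' @param n_coupled number of 28m DE genes linearly coupled to latent
#'   function.
#' @param coupling_strength |coupling coefficient| (log2 units per latent
#'   unit); the sign opposes the gene's age log2fc, so genes that rise
#'   with age fall with function (the antagonistic mode).
#' @param coupling_sd per-sample log2 noise added to coupled genes.
#' @param function_decline named per-group mean latent-function shift
#'   (reference 0; more negative = worse function).
#' @param latent_sd within-group sd of latent function.
#' @param two_run if TRUE, reference libraries are re-prepared for each
#'   old-group run (technical replicates kept separate).
#' @param seed master integer seed; all streams derive from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c("6m" = 7L, "24m" = 7L, "28m" = 8L),
                       n_genes = 2000L,
                       frac_de_24m = 0.01, frac_de_28m = 0.08,
                       log2fc_mean = 1.5, log2fc_sd = 0.5,
                       dispersion_a0 = 0.05, dispersion_a1 = 2,
                       libsize_sigma = 0.15,
                       n_coupled = 40L,
                       coupling_strength = 0.25, coupling_sd = 0.25,
                       function_decline = c("6m" = 0, "24m" = -4,
                                            "28m" = -8),
                       latent_sd = 2.5,
                       two_run = TRUE,
                       seed = 1L) {
  cfg <- list(n_per_group = n_per_group, n_genes = as.integer(n_genes),
              frac_de_24m = frac_de_24m, frac_de_28m = frac_de_28m,
              log2fc_mean = log2fc_mean, log2fc_sd = log2fc_sd,
              dispersion_a0 = dispersion_a0, dispersion_a1 = dispersion_a1,
              libsize_sigma = libsize_sigma,
              n_coupled = as.integer(n_coupled),
              coupling_strength = coupling_strength,
              coupling_sd = coupling_sd,
              function_decline = function_decline, latent_sd = latent_sd,
              two_run = isTRUE(two_run), seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (is.null(names(cfg$n_per_group)) || any(names(cfg$n_per_group) == ""))
    stop_domain("n_per_group must be named by age group")
  if (any(cfg$n_per_group < 2))
    stop_domain("each group needs >= 2 animals")
  if (length(cfg$n_per_group) < 2)
    stop_domain("need a reference and >= 1 old group")
  for (f in c("frac_de_24m", "frac_de_28m"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_domain(f, " must lie in [0, 1]")
  de_groups <- setdiff(names(cfg$n_per_group), names(cfg$n_per_group)[1])
  max_de <- floor(cfg$frac_de_28m * cfg$n_genes)
  if ("28m" %in% de_groups && cfg$n_coupled > max_de)
    stop_domain("n_coupled exceeds the number of 28m DE genes (",
                max_de, ")")
  if (cfg$dispersion_a0 < 0 || cfg$dispersion_a1 < 0)
    stop_domain("dispersion trend parameters must be >= 0")
  if (!all(names(cfg$n_per_group) %in% names(cfg$function_decline)))
    stop_domain("function_decline must name every group")
  if (cfg$libsize_sigma < 0 || cfg$latent_sd < 0 || cfg$coupling_sd < 0)
    stop_domain("scale parameters must be >= 0")
  invisible(cfg)
}

# Determinant generation parameters: baseline level (raw units) and a
# shared multiplicative response to latent function. Baselines echo
# typical adult C57BL/6 values: rotarod ~124 s, grip ~100 gf, inverted
# cling ~63 s, treadmill max ~25 m/min, wheel running ~5 km/day.
# Slope and noise are calibrated so that (i) a reference determinant's
# CV on the log scale is ~0.23 (the printed rotarod reference 28.9/123.9)
# and (ii) the composite tracks latent function closely enough that a
# tightly coupled gene can reach |R| ~ 0.9 against observed CFAB at
# study sample sizes, as the strongest associations do.
DETERMINANT_BASELINES <- c(rotarod_s = 124, grip_force = 100,
                           inverted_cling_s = 63, treadmill_speed = 25,
                           vwr = 5)
DETERMINANT_SLOPE <- 0.046  # log-units per latent-function unit
DETERMINANT_NOISE <- 0.20   # log-scale measurement noise sd

#' Generate functional-test records with a latent function value
#'
#' Each animal draws a latent function value (group mean shift + normal
#' noise); each of the five determinants is then a monotone increasing
#' function of latent function with lognormal measurement noise, so all
#' raw measurements are strictly positive. Observed CFAB must be computed
#' from these records via [reference_stats()]/[cfab_table()] — the latent
#' value itself is ground truth, never handed downstream.
#'
#' @param config a `sim_config`.
#' @return list: `records` (data.frame animal_id, age_group, ta_mass_mg,
#'   five determinants), `latent` (named per-animal latent values).
#' @export
generate_function_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  groups <- names(config$n_per_group)
  animal_id <- unlist(lapply(groups, function(g)
    sprintf("%s_a%02d", g, seq_len(config$n_per_group[[g]]))))
  age_group <- rep(groups, config$n_per_group)
  n <- length(animal_id)
  latent <- config$function_decline[age_group] +
    rnorm(n, 0, config$latent_sd)
  names(latent) <- animal_id
  det <- sapply(names(DETERMINANT_BASELINES), function(d)
    DETERMINANT_BASELINES[[d]] *
      exp(DETERMINANT_SLOPE * latent + rnorm(n, 0, DETERMINANT_NOISE)))
  # TA mass declines with function too (~58 mg young, ~43 mg at 28m)
  ta_mass_mg <- 58 * exp(0.04 * latent + rnorm(n, 0, 0.05))
  records <- data.frame(animal_id = animal_id, age_group = age_group,
                        ta_mass_mg = ta_mass_mg, det,
                        stringsAsFactors = FALSE)
  list(records = records, latent = latent)
}

#' Generate NB counts, sample metadata, and the ground-truth table
#'
#' Counts are negative binomial with mean `mu_gj = s_j q_g 2^(x_gj)` and
#' variance `mu + alpha mu^2`, where `x_gj` is the gene's group log2
#' fold change plus, for coupled genes, `coupling * latent_j` (latent
#' centered on the reference group) plus log2 noise. Per-gene dispersion
#' follows the trend `a0 + a1/q_g`. In two-run mode the reference animals
#' contribute one independently re-generated library per run, emulating
#' re-prepared technical replicates kept separate in analysis.
#'
#' @param config a `sim_config`.
#' @param latent named per-animal latent function values from
#'   [generate_function_data()].
#' @return list: `counts` (integer matrix genes x samples), `meta`
#'   (data.frame sample_id, animal_id, age_group, run), `truth` (list
#'   `genes` with per-gene q, lfc per contrast, coupling, realized
#'   true_lfc per contrast, true_r per contrast; `samples` with latent
#'   and size factor).
#' @export
generate_counts <- function(config, latent) {
  stopifnot(inherits(config, "sim_config"))
  groups <- names(config$n_per_group)
  ref <- groups[1]
  animal_group <- rep(groups, config$n_per_group)
  animal_id <- unlist(lapply(groups, function(g)
    sprintf("%s_a%02d", g, seq_len(config$n_per_group[[g]]))))
  if (!all(animal_id %in% names(latent)))
    stop_domain("latent values missing for some animals")
  set.seed(derive_seed(config$seed, 2L))

  old_groups <- setdiff(groups, ref)
  # one sequencing run per old group; reference libraries re-prepared
  # per run (or a single run when two_run = FALSE / one old group)
  runs <- if (config$two_run) seq_along(old_groups) else 1L
  meta <- do.call(rbind, lapply(runs, function(r) {
    grp_in_run <- if (config$two_run) c(ref, old_groups[r])
                  else c(ref, old_groups)
    idx <- animal_group %in% grp_in_run
    data.frame(sample_id = sprintf("%s_run%d", animal_id[idx], r),
               animal_id = animal_id[idx],
               age_group = animal_group[idx],
               run = paste0("run", r), stringsAsFactors = FALSE)
  }))
  n_samp <- nrow(meta)
  ng <- config$n_genes
  gene_id <- sprintf("g%06d", seq_len(ng))

  # baseline expression levels, lognormal across genes
  q <- exp(rnorm(ng, log(50), 1.7))

  draw_lfc <- function(frac) {
    lfc <- numeric(ng)
    n_de <- floor(frac * ng)
    if (n_de > 0) {
      idx <- sample.int(ng, n_de)
      sign <- ifelse(rbinom(n_de, 1, 0.5) == 1, 1, -1)
      lfc[idx] <- sign * abs(rnorm(n_de, config$log2fc_mean,
                                   config$log2fc_sd))
    }
    lfc
  }
  lfc <- sapply(old_groups, function(g)
    draw_lfc(if (g == "24m") config$frac_de_24m else config$frac_de_28m))
  lfc <- matrix(lfc, nrow = ng, dimnames = list(gene_id, old_groups))

  # coupled genes: chosen among the 28m (or last old group) DE genes,
  # coupling sign opposing the age effect
  couple_group <- if ("28m" %in% old_groups) "28m" else old_groups[length(old_groups)]
  coupling <- numeric(ng)
  de_idx <- which(lfc[, couple_group] != 0)
  if (config$n_coupled > 0) {
    if (config$n_coupled > length(de_idx))
      stop_domain("n_coupled exceeds DE genes in ", couple_group)
    cp <- sample(de_idx, config$n_coupled)
    coupling[cp] <- -sign(lfc[cp, couple_group]) * config$coupling_strength
  }

  sf <- exp(rnorm(n_samp, 0, config$libsize_sigma))
  sf <- sf / exp(mean(log(sf)))  # geometric mean 1
  names(sf) <- meta$sample_id

  lat_s <- latent[meta$animal_id] - config$function_decline[[ref]]
  grp_s <- meta$age_group
  # per-gene, per-sample log2 signal
  x <- matrix(0, ng, n_samp)
  for (g in old_groups) x[, grp_s == g] <- lfc[, g]
  is_cp <- coupling != 0
  if (any(is_cp)) {
    x[is_cp, ] <- x[is_cp, ] + outer(coupling[is_cp], lat_s) +
      matrix(rnorm(sum(is_cp) * n_samp, 0, config$coupling_sd),
             sum(is_cp), n_samp)
  }
  mu <- sweep(q * 2^x, 2, sf, "*")
  if (any(!is.finite(mu))) stop_domain("non-finite NB mean generated")
  alpha <- pmax(config$dispersion_a0 + config$dispersion_a1 / q, 0)
  counts <- matrix(0L, ng, n_samp, dimnames = list(gene_id, meta$sample_id))
  for (i in seq_len(ng)) {
    counts[i, ] <- if (alpha[i] < 1e-12) rpois(n_samp, mu[i, ])
                   else rnbinom(n_samp, mu = mu[i, ], size = 1 / alpha[i])
  }

  # realized contrast effects and construction-level correlation with
  # latent function, per contrast (expected log2 signal, noise-free)
  truth_genes <- data.frame(gene_id = gene_id, q = q,
                            coupling = coupling,
                            stringsAsFactors = FALSE)
  for (g in old_groups) {
    truth_genes[[paste0("lfc_", g)]] <- lfc[, g]
    truth_genes[[paste0("true_lfc_", g)]] <- lfc[, g] +
      coupling * (config$function_decline[[g]] - config$function_decline[[ref]])
    in_c <- grp_s %in% c(ref, g) & (!config$two_run |
             meta$run == paste0("run", match(g, old_groups)))
    sig <- matrix(0, ng, sum(in_c))
    sig[, grp_s[in_c] == g] <- lfc[, g]
    sig <- sig + outer(coupling, lat_s[in_c])
    lat_c <- lat_s[in_c]
    r <- apply(sig, 1, function(s)
      if (sd(s) == 0) NA_real_ else cor(s, lat_c))
    truth_genes[[paste0("true_r_", g)]] <- r
  }
  truth_samples <- data.frame(sample_id = meta$sample_id,
                              latent = unname(latent[meta$animal_id]),
                              size_factor = unname(sf),
                              stringsAsFactors = FALSE)
  list(counts = counts, meta = meta,
       truth = list(genes = truth_genes, samples = truth_samples))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: functional records (+ latent ground truth), then
#' counts, metadata and truth from the same configuration.
#'
#' @param config a `sim_config` (default configuration if omitted).
#' @return list: `records`, `latent`, `counts`, `meta`, `truth`,
#'   `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  fd <- generate_function_data(config)
  cn <- generate_counts(config, fd$latent)
  c(fd, cn, list(config = config))
}
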