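# Coefficient calibration: turns a declarative scenario description into
# generator coefficients whose latent-scale variance decomposition reproduces
# the requested APC and per-mediator effect shares.

# Category-index distributions implied by uniform continuous age/period.
# Centered index variables x = idx - (n + 1)/2 are the working covariates.
category_distributions <- function(scheme) {
  na <- scheme$n_age
  np <- scheme$n_period
  nc <- scheme$n_cohort
  xa <- seq_len(na) - (na + 1) / 2
  xp <- seq_len(np) - (np + 1) / 2
  xc <- seq_len(nc) - (nc + 1) / 2
  pa <- rep(1 / na, na)
  pp <- rep(1 / np, np)
  pc <- numeric(nc)
  for (a in seq_len(na)) {
    for (p in seq_len(np)) {
      k <- p - a + na
      pc[k] <- pc[k] + pa[a] * pp[p]
    }
  }
  list(
    xa = xa, xp = xp, xc = xc, pa = pa, pp = pp, pc = pc,
    var_xa = sum(pa * xa^2), var_xp = sum(pp * xp^2), var_xc = sum(pc * xc^2)
  )
}

wvar <- function(x, w) sum(w * (x - sum(w * x))^2)
wcov <- function(x, y, w) sum(w * (x - sum(w * x)) * (y - sum(w * y)))

# Mean of a binary mediator per period category with other parents held at
# their population-average latent contribution (the one-at-a-time convention
# used throughout calibration and attribution).
binary_period_means <- function(spec, htil, g_g, prev, linkinv) {
  linkinv(spec$lat0 + (g_g %||% 0) * prev + spec$g_p * htil)
}

#' Calibrate generator coefficients to a scenario
#'
#' Chooses coefficient scales so that, on the latent linear-predictor scale,
#' the variances of the age, period-mediated and cohort contributions match
#' the configured shares; within the period-mediated contribution the
#' per-mediator variance shares match `mediator_shares`; in `more_causes` the
#' age-via-BMI (cohort-via-smoking) contribution carries the configured
#' fraction of the total age (cohort) contribution variance; and the outcome
#' intercept reproduces the baseline risk targets. The overall latent scale is
#' anchored so that, at the default 70% age share, the systematic age gradient
#' spans the link-transformed risk targets after correcting for the
#' attenuation that non-age latent variation induces in marginal
#' probabilities.
#'
#' @param config a [scenario_config()].
#' @return an object of class `generator_params`.
#' @export
#' @examples
#' params <- calibrate(scenario_config("simple", "probit", n = 1000))
#' params
calibrate <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  anchor <- c(age = 0.70, period = 0.20, cohort = 0.10)
  v_tot_fixed <- NULL
  if (!isTRUE(all.equal(unname(config$shares), unname(anchor),
    tolerance = 1e-12
  ))) {
    # Non-default share configurations redistribute effect within the total
    # APC latent variance of the anchor (default-shares) world, so effect-size
    # sweeps change composition, not overall scale.
    ref <- config
    ref$shares <- anchor
    v_tot_fixed <- calibrate(ref)$v_tot
  }
  scenario <- config$scenario
  variant <- config$variant
  scheme <- config$scheme
  lk <- variant_links(variant)
  dist <- category_distributions(scheme)
  specs <- default_mediator_specs(variant)
  prev <- if (scenario == "confounding") config$genotype_prevalence else 0
  htil <- lapply(specs, period_transform, n_period = scheme$n_period)

  shares <- config$shares
  mshares <- config$mediator_shares
  if (scenario == "more_causes" && shares[["period"]] == 0 &&
    (config$age_to_bmi_share > 0 || config$cohort_to_smoking_share > 0)) {
    stop(paste(
      "infeasible shares: a zero period share leaves no BMI/smoking outcome",
      "pathway to route age/cohort effects through in 'more_causes'"
    ), call. = FALSE)
  }

  targets <- lk$linkfun(config$baseline_risk_targets)
  span <- targets[2] - targets[1]
  xa_range <- max(dist$xa) - min(dist$xa)
  # The latent scale is anchored so that the *observed* per-age-category risk
  # gradient matches the targets at the default 70/20/10 shares. Because of
  # the linear identity (c_idx = p_idx - a_idx + n_age), the observed age
  # curve carries the cohort slope with opposite sign, so the anchor gradient
  # is alpha - theta, not alpha alone.
  anchor_grad <- sqrt(0.70 / dist$var_xa) + sqrt(0.10 / dist$var_xc)

  atten <- 1
  for (iter in 1:8) {
    v_tot <- if (!is.null(v_tot_fixed)) {
      v_tot_fixed
    } else {
      (span * atten / xa_range / anchor_grad)^2
    }
    v_age <- shares[["age"]] * v_tot
    v_per <- shares[["period"]] * v_tot
    v_coh <- shares[["cohort"]] * v_tot

    # genotype effects (confounding only); outcome coefficient scales with the
    # total APC latent SD, mediator effects are fixed spec constants
    delta_g <- if (scenario == "confounding") 0.45 * sqrt(v_tot) else 0

    # --- mediator outcome coefficients (deltas) ---------------------------
    mu_p <- list() # period-part mean function per mediator, over categories
    for (m in names(specs)) {
      sp <- specs[[m]]
      mu_p[[m]] <- if (sp$kind == "continuous") {
        sp$g_p * htil[[m]]
      } else {
        binary_period_means(sp, htil[[m]], sp$g_g, prev, lk$linkinv)
      }
    }
    v_m <- vapply(mu_p, function(mu) wvar(mu, dist$pp), numeric(1))
    dtil <- numeric(length(specs))
    names(dtil) <- names(specs)
    for (m in names(specs)) {
      dtil[m] <- if (mshares[[m]] > 0 && v_m[[m]] > 0) {
        specs[[m]]$sign_y * sqrt(mshares[[m]] / v_m[[m]])
      } else {
        0
      }
    }
    gsum <- Reduce(`+`, Map(function(d, mu) d * mu, dtil, mu_p))
    s2 <- wvar(gsum, dist$pp)
    scale_d <- if (v_per > 0 && s2 > 0) sqrt(v_per / s2) else 0
    delta <- dtil * scale_d

    # --- age side ---------------------------------------------------------
    t_age <- sqrt(v_age / dist$var_xa) # total age slope (positive)
    g_a <- 0
    if (scenario == "more_causes" && config$age_to_bmi_share > 0) {
      if (delta[["bmi"]] == 0) {
        stop("infeasible: age_to_bmi_share > 0 but BMI carries no outcome effect",
          call. = FALSE
        )
      }
      ind <- -sqrt(config$age_to_bmi_share) * t_age # negative age->BMI path
      g_a <- ind / delta[["bmi"]]
      alpha_direct <- t_age - ind
    } else {
      alpha_direct <- t_age
    }

    # --- cohort side ------------------------------------------------------
    # The routed cohort-via-smoking share is defined on the link (path-
    # product) scale where mediated effects are estimated: smoking is binary,
    # so its latent coefficient and its contribution to outcome probabilities
    # live on different scales, and the path product delta * g_c is the
    # estimand-scale pathway. theta_direct is then set so the probability-
    # scale cohort contribution still carries exactly its variance share.
    g_c <- 0
    if (scenario == "more_causes" && config$cohort_to_smoking_share > 0 &&
      v_coh > 0) {
      if (delta[["smoking"]] == 0) {
        stop("infeasible: cohort_to_smoking_share > 0 but smoking carries no outcome effect",
          call. = FALSE
        )
      }
      # parametrize by the magnitude t of the total latent cohort slope:
      # indirect (path product) = sqrt(share)*t, direct = -(1 + sqrt(share))*t;
      # t is solved so the probability-scale cohort contribution carries
      # exactly its variance share v_coh
      sp <- specs$smoking
      rt <- sqrt(config$cohort_to_smoking_share)
      base <- lk$linkinv(sp$lat0 + (sp$g_g %||% 0) * prev)
      coh_var <- function(t) {
        g_c_t <- rt * t / abs(delta[["smoking"]])
        s_fun <- delta[["smoking"]] *
          (lk$linkinv(sp$lat0 + (sp$g_g %||% 0) * prev + g_c_t * dist$xc) - base)
        wvar(-(1 + rt) * t * dist$xc + s_fun, dist$pc)
      }
      up <- sqrt(v_coh / dist$var_xc)
      while (coh_var(up) < v_coh) up <- up * 2
      t_coh <- stats::uniroot(
        function(t) coh_var(t) - v_coh, c(0, up),
        tol = 1e-12
      )$root
      g_c <- rt * t_coh / abs(delta[["smoking"]])
      theta_direct <- -(1 + rt) * t_coh
    } else {
      theta_direct <- -sqrt(v_coh / dist$var_xc)
    }

    # --- assemble and tune against the marginal risk curve ----------------
    mediators <- list()
    for (m in names(specs)) {
      sp <- specs[[m]]
      sp$delta <- unname(delta[[m]])
      sp$g_a <- if (m == "bmi") g_a else 0
      sp$g_c <- if (m == "smoking") g_c else 0
      if (scenario != "confounding") sp$g_g <- 0
      sp$g_g <- sp$g_g %||% 0
      sp$htil <- htil[[m]]
      mediators[[m]] <- sp
    }
    params <- structure(
      list(
        scenario = scenario, variant = variant, scheme = scheme,
        config = config,
        v_tot = v_tot, v_age = v_age, v_period = v_per, v_cohort = v_coh,
        attenuation = atten,
        alpha_direct = alpha_direct, theta_direct = theta_direct,
        delta_g = delta_g, genotype_prevalence = prev,
        sigma_y = if (variant == "linear") sqrt(v_tot) else 0,
        delta0 = 0,
        mediators = mediators
      ),
      class = "generator_params"
    )
    # Internal calibration draws: per-age mean outcome probabilities under the
    # candidate coefficients (expectations of the inverse link, so the Monte
    # Carlo error is far below event-count noise). The intercept is solved so
    # the population mean outcome equals the mean of the interpolated
    # risk-target curve; the latent scale is then adjusted until the realized
    # marginal age-risk span matches the link-transformed targets, which
    # accounts exactly for the attenuation that mediator noise, period and
    # cohort variation induce in marginal probabilities.
    df <- with_local_seed(derive_seed(config$seed, "calibrate"), {
      m_draw <- 60000L
      df <- data.frame(
        a_idx = sample.int(scheme$n_age, m_draw, replace = TRUE),
        p_idx = sample.int(scheme$n_period, m_draw, replace = TRUE)
      )
      df$c_idx <- df$p_idx - df$a_idx + scheme$n_age
      if (scenario == "confounding") {
        df$genotype <- stats::rbinom(m_draw, 1, prev)
      }
      draw_mediators(params, df)
    })
    lp <- latent_outcome(params, df) # delta0 still 0
    lin <- targets[1] +
      (seq_len(scheme$n_age) - 1) / max(scheme$n_age - 1, 1) * span
    qbar <- mean(lk$linkinv(lin))
    d0 <- if (variant == "linear") {
      qbar - mean(lp)
    } else {
      stats::uniroot(
        function(d) mean(lk$linkinv(d + lp)) - qbar, c(-60, 60),
        tol = 1e-10
      )$root
    }
    params$delta0 <- d0
    if (!is.null(v_tot_fixed)) break # scale inherited from the anchor world
    p_age <- tapply(lk$linkinv(d0 + lp), df$a_idx, mean)
    realized <- lk$linkfun(p_age[[scheme$n_age]]) - lk$linkfun(p_age[[1]])
    if (abs(realized - span) < 0.002 * abs(span)) break
    atten <- atten * span / realized
  }
  params
}

# Latent linear predictor pieces, shared by the generator, the intercept
# tuner and the attribution decomposition. `df` needs a_idx, p_idx, c_idx,
# mediator columns (for `latent_outcome`) and genotype when relevant.
centered_idx <- function(idx, n) idx - (n + 1) / 2

mediator_latent <- function(params, m, df) {
  sp <- params$mediators[[m]]
  sch <- params$scheme
  xa <- centered_idx(df$a_idx, sch$n_age)
  xc <- centered_idx(df$c_idx, sch$n_cohort)
  g <- if (!is.null(df$genotype)) df$genotype else 0
  base <- if (sp$kind == "continuous") sp$m0 else sp$lat0
  base + sp$htil[df$p_idx] * sp$g_p + sp$g_a * xa + sp$g_c * xc + sp$g_g * g
}

latent_outcome <- function(params, df) {
  sch <- params$scheme
  xa <- centered_idx(df$a_idx, sch$n_age)
  xc <- centered_idx(df$c_idx, sch$n_cohort)
  lp <- params$delta0 + params$alpha_direct * xa + params$theta_direct * xc
  for (m in names(params$mediators)) {
    lp <- lp + params$mediators[[m]]$delta * df[[m]]
  }
  if (!is.null(df$genotype)) lp <- lp + params$delta_g * df$genotype
  lp
}

#' @export
print.generator_params <- function(x, ...) {
  cat(sprintf(
    "Generator parameters: scenario '%s', %s variant\n", x$scenario, x$variant
  ))
  cat(sprintf(
    "  latent variances: total %.4f (age %.4f, period %.4f, cohort %.4f)\n",
    x$v_tot, x$v_age, x$v_period, x$v_cohort
  ))
  cat(sprintf(
    "  alpha_direct %.4f, theta_direct %.4f, delta0 %.3f%s\n",
    x$alpha_direct, x$theta_direct, x$delta0,
    if (x$delta_g != 0) sprintf(", delta_genotype %.3f", x$delta_g) else ""
  ))
  d <- vapply(x$mediators, `[[`, numeric(1), "delta")
  cat(
    "  mediator outcome coefficients:",
    paste(sprintf("%s %.3f", names(d), d), collapse = ", "), "\n"
  )
  invisible(x)
}
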