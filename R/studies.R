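## The model-variation studies and their evaluation metrics: stance
## masking, stance RMSE against reference curves, RMSE differences as a
## percentage of signal range, the locked-toes comparison, the
## Achilles-tendon stiffness sweep, and the mass-distribution /
## contact-height sensitivity grid.

#' Stance mask from a vertical GRF series
#'
#' @param vgrf vertical ground reaction force over one gait cycle (N).
#' @param threshold stance force threshold (N), default 20.
#' @return list with `mask` (logical) and `fraction` (stance samples /
#'   cycle samples).
#' @export
stance_mask <- function(vgrf, threshold = 20) {
  mask <- vgrf > threshold
  list(mask = mask, fraction = mean(mask))
}

#' Stance-phase RMSE between a simulated and a reference curve
#'
#' Both curves must be sampled on the same 0-100% gait-cycle grid.
#'
#' @param sim simulated curve.
#' @param ref reference mean curve.
#' @param mask logical stance mask on the same grid.
#' @return RMSE in the curve's units.
#' @export
rmse_stance <- function(sim, ref, mask) {
  stopifnot(length(sim) == length(ref), length(mask) == length(sim))
  if (!any(mask)) stop("empty stance mask")
  sqrt(mean((sim[mask] - ref[mask])^2))
}

#' RMSE difference as a percentage of the reference stance range
#'
#' `(rmse_b - rmse_a) / (max - min of the reference over stance) * 100`;
#' negative values are improvements of condition b over condition a.
#'
#' @param rmse_a,rmse_b RMSEs of the two conditions against the same
#'   reference.
#' @param ref reference mean curve.
#' @param mask logical stance mask.
#' @return signed percentage.
#' @export
delta_rmse_percent <- function(rmse_a, rmse_b, ref, mask) {
  rng <- diff(range(ref[mask]))
  if (rng == 0) stop("reference has zero range over stance")
  (rmse_b - rmse_a) / rng * 100
}

## Standard per-solution metric row.
solution_metrics <- function(sol, ref = NULL) {
  v <- sol$grf$r$Fy
  sm <- stance_mask(v)
  sw <- stance_window(v)
  peak <- if (any(sw$stance)) {
    seg_end <- which(!sw$stance)[1]
    seg <- sw$v[seq_len(if (is.na(seg_end)) length(sw$v) else seg_end - 1L)]
    first_vertical_peak(seg)
  } else NA_real_
  out <- data.frame(cot = sol$cot, stride_length = sol$stride_length,
                    cycle_duration = sol$cycle_duration,
                    stance_fraction = sm$fraction, first_vgrf_peak = peak,
                    objective = sol$objective, status = sol$status,
                    iterations = sol$iterations)
  if (!is.null(ref)) {
    for (sig in c("knee_r", "ankle_r")) {
      if (!(sig %in% names(ref$signals)) ||
          !(sig %in% sol$coord_names)) next
      simc <- sol$cycle_q[match(sig, sol$coord_names), ]
      refc <- ref$signals[[sig]]$mean
      refmask <- stance_mask(ref$signals$grf_vy_r$mean)$mask
      out[[paste0("rmse_", sig)]] <- rmse_stance(simc, refc, refmask)
    }
  }
  out
}

new_study_result <- function(kind, conditions, solutions, metrics,
                             extra = list()) {
  structure(c(list(kind = kind, conditions = conditions,
                   solutions = solutions, metrics = metrics), extra),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<%s study: %d condition(s)>\n", x$kind, nrow(x$metrics)))
  print(x$metrics)
  invisible(x)
}

#' Toe-joint study
#'
#' Solves the predictive gait problem with free toe (MTP) joints and with
#' the toes locked (hinges replaced by welds at neutral), the locked
#' condition warm-started from the free-toes solution, and tabulates the
#' paired metrics, the cost-of-transport difference, and its per-muscle-
#' group breakdown.
#'
#' @param m a `predgait_model` with toe joints.
#' @param config an [ocp_config()].
#' @param ref optional reference gait (synthesized when NULL).
#' @param groups named muscle groups for the breakdown; defaults to the
#'   model's muscle `group` labels.
#' @return a `study_result` with `$delta_cot` and `$group_share`.
#' @export
toe_study <- function(m, config, ref = NULL, groups = NULL) {
  toe_coords <- m$coord_names[vapply(m$coordinates, `[[`, TRUE, "is_toe")]
  if (length(toe_coords) == 0) config_error("model has no toe joints")
  if (is.null(ref)) ref <- make_reference_gait(seed = config$seed)
  sol_toes <- solve_gait(m, config, ref = ref)
  m_locked <- apply_variant(m, model_variant(toes_locked = TRUE))
  ## warm start the locked condition from the toes solution
  geom_l <- fit_all_muscles(m_locked)
  cfg_l <- config
  ocp_t <- transcribe(m, config)
  ocp_l <- transcribe(m_locked, cfg_l, geom_l)
  zt <- ocp_pack(ocp_t, sol_toes$X, sol_toes$UA, sol_toes$DFT, sol_toes$E,
                 sol_toes$tf)
  zl <- z_map_model(ocp_t, ocp_l, zt)
  sol_locked <- solve_gait(m_locked, cfg_l, ref = ref, geom = geom_l,
                           warm = zl)
  if (is.null(groups)) {
    glab <- vapply(m$muscles, `[[`, "", "group")
    groups <- split(vapply(m$muscles, `[[`, "", "name"), glab)
  }
  metrics <- rbind(cbind(condition = "toes",
                         solution_metrics(sol_toes, ref)),
                   cbind(condition = "toes_locked",
                         solution_metrics(sol_locked, ref)))
  new_study_result("toe", c("toes", "toes_locked"),
                   list(toes = sol_toes, toes_locked = sol_locked), metrics,
                   extra = list(
                     delta_cot = sol_toes$cot - sol_locked$cot,
                     group_share = per_group_breakdown(sol_locked, sol_toes,
                                                      groups)))
}

#' Achilles-tendon stiffness sweep
#'
#' Solves the gait problem for tendon stiffness fractions of the generic
#' value applied to the triceps surae, descending from the first fraction
#' with each condition warm-started from its neighbor (the first condition
#' uses the standard multi-guess driver).  The tendon curve shift is
#' recomputed per fraction so the force at slack length is invariant.
#'
#' @param m a `predgait_model`.
#' @param fractions stiffness fractions, default `seq(1.0, 0.3, by = -0.1)`.
#' @param config an [ocp_config()].
#' @param ref optional reference gait.
#' @return a `study_result`; `$metrics` has one row per fraction and
#'   `$triceps` holds activation and normalized-fiber-length trajectories.
#' @export
tendon_sweep <- function(m, fractions = seq(1.0, 0.3, by = -0.1), config,
                         ref = NULL) {
  stopifnot(all(diff(fractions) < 0))
  if (is.null(ref)) ref <- make_reference_gait(seed = config$seed)
  sols <- list()
  rows <- list()
  triceps <- list()
  z_prev <- NULL; ocp_prev <- NULL
  for (fr in fractions) {
    mv <- apply_variant(m, model_variant(tendon_stiffness_fraction = fr))
    geom <- fit_all_muscles(mv)
    ocp_v <- transcribe(mv, config, geom)
    sol <- tryCatch({
      if (is.null(z_prev)) solve_gait(mv, config, ref = ref, geom = geom)
      else solve_gait(mv, config, ref = ref, geom = geom,
                      warm = z_map_model(ocp_prev, ocp_v, z_prev))
    }, error = function(e) NULL)
    key <- sprintf("%.2f", fr)
    sols[[key]] <- sol
    if (!is.null(sol)) {
      z_prev <- ocp_pack(ocp_v, sol$X, sol$UA, sol$DFT, sol$E, sol$tf)
      ocp_prev <- ocp_v
      tri <- grep("gastroc_r|soleus_r", sol$muscle_names)
      triceps[[key]] <- list(
        activation = sol$cycle_act[tri, , drop = FALSE],
        lm_tilde = tendon_fiber_lengths(mv, sol, tri))
      rows[[length(rows) + 1L]] <-
        cbind(fraction = fr, solution_metrics(sol, ref))
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(fraction = fr, cot = NA, stride_length = NA,
                   cycle_duration = NA, stance_fraction = NA,
                   first_vgrf_peak = NA, objective = NA, status = "error",
                   iterations = NA)
    }
  }
  new_study_result("tendon_sweep", sprintf("%.2f", fractions), sols,
                   do.call(rbind, rows), extra = list(triceps = triceps))
}

## Normalized fiber lengths along the reconstructed cycle for a muscle
## subset (tendon-force states + geometry; zero tendon-force rate).
tendon_fiber_lengths <- function(m, sol, idx) {
  pv <- muscle_param_vectors(m)
  geom <- fit_all_muscles(m)
  out <- matrix(0, length(idx), length(sol$cycle_frac))
  for (k in seq_along(idx)) {
    i <- idx[k]
    g <- geom$muscles[[i]]
    lmt <- mtu_length(g, sol$cycle_q)
    ft <- sol$cycle_ft[i, ]
    lt <- tendon_length(ft, pv$k[i], pv$shift[i]) * pv$l_slack[i]
    w <- pv$l_opt[i] * sin(pv$alpha_opt[i])
    out[k, ] <- sqrt(pmax(lmt - lt, 0.05 * pv$l_opt[i])^2 + w^2) /
      pv$l_opt[i]
  }
  out
}

#' Mass-distribution / contact-height sensitivity study
#'
#' 2 x 2 grid: baseline vs lighter-torso/heavier-legs mass distribution,
#' and low vs raised (~1 cm) contact spheres; off-baseline conditions are
#' warm-started from the baseline solution.
#'
#' @param m a `predgait_model`.
#' @param config an [ocp_config()].
#' @param mass_delta torso mass change (kg) for the "light torso"
#'   conditions; default -6.1 (a generic-model torso reduction of ~10% body
#'   mass, scaled to the fixture).
#' @param contact_offset vertical sphere raise (m), default +0.01.
#' @param ref optional reference gait.
#' @return a `study_result` with one row per grid cell.
#' @export
mass_contact_study <- function(m, config, mass_delta = -6.1,
                               contact_offset = 0.01, ref = NULL) {
  if (is.null(ref)) ref <- make_reference_gait(seed = config$seed)
  grid <- list(
    base_low = model_variant(),
    light_low = model_variant(torso_mass_delta = mass_delta),
    base_high = model_variant(contact_vertical_offset = contact_offset),
    light_high = model_variant(torso_mass_delta = mass_delta,
                               contact_vertical_offset = contact_offset))
  sols <- list(); rows <- list()
  z_base <- NULL; ocp_base <- NULL
  for (nmx in names(grid)) {
    mv <- apply_variant(m, grid[[nmx]])
    geom <- fit_all_muscles(mv)
    ocp_v <- transcribe(mv, config, geom)
    sol <- tryCatch({
      if (is.null(z_base)) solve_gait(mv, config, ref = ref, geom = geom)
      else solve_gait(mv, config, ref = ref, geom = geom,
                      warm = z_map_model(ocp_base, ocp_v, z_base))
    }, error = function(e) NULL)
    sols[[nmx]] <- sol
    if (!is.null(sol) && is.null(z_base)) {
      z_base <- ocp_pack(ocp_v, sol$X, sol$UA, sol$DFT, sol$E, sol$tf)
      ocp_base <- ocp_v
    }
    rows[[length(rows) + 1L]] <- if (!is.null(sol))
      cbind(condition = nmx, solution_metrics(sol, ref))
    else data.frame(condition = nmx, cot = NA, stride_length = NA,
                    cycle_duration = NA, stance_fraction = NA,
                    first_vgrf_peak = NA, objective = NA, status = "error",
                    iterations = NA)
  }
  new_study_result("mass_contact", names(grid), sols, do.call(rbind, rows))
}
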