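# Bottom-up / top-down coupling: Poisson GLMMs of one group's sun-anchored
# hourly counts on another's, with protected-area random intercepts.

#' Fit a predator-prey hourly coupling model
#'
#' Poisson GLMM `log E[response] = alpha + beta * predictor + b_area`,
#' `b_area ~ N(0, sigma^2)`, fitted by Laplace-approximated ML
#' ([lme4::glmer()]). A significant positive `beta` (Wald 95% CI above 0)
#' is read as bottom-up coupling (the response group tracks the predictor's
#' activity), a significant negative one as top-down avoidance. The
#' predictor enters as the raw hourly count (effect per event); set
#' `scale_predictor = TRUE` to standardise it. With a single protected area
#' the model degrades to a fixed-effects Poisson regression with a warning.
#'
#' @param pairs data.frame with `protected_area`, `anchored_hour`,
#'   `response_count`, `predictor_count` (24 rows per area).
#' @param response_name,predictor_name labels used in output and error
#'   messages.
#' @param scale_predictor standardise the predictor, default FALSE.
#' @param offset_log_effort optional per-row log-effort offset.
#' @param level confidence level of the Wald interval.
#' @return one-row data.frame: `response_group`, `predictor_group`, `beta`,
#'   `se`, `ci_lo`, `ci_hi`, `direction` (`bottom_up` / `top_down` /
#'   `none`), `n_response`, `n_predictor`, `sites_used`.
#' @export
fit_coupling <- function(pairs, response_name = "response",
                         predictor_name = "predictor",
                         scale_predictor = FALSE, offset_log_effort = NULL,
                         level = 0.95) {
  need <- c("protected_area", "anchored_hour", "response_count",
            "predictor_count")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns ", paste(need, collapse = ", "))
  }
  if (sum(pairs$response_count) == 0) {
    stop("response group '", response_name, "' has no events")
  }
  d <- pairs
  d$x <- if (scale_predictor) drop(scale(d$predictor_count)) else
    d$predictor_count
  n_area <- length(unique(d$protected_area))
  lab <- paste(response_name, "~", predictor_name)
  if (n_area >= 2) {
    fit <- withCallingHandlers(
      tryCatch(
        lme4::glmer(response_count ~ x + (1 | protected_area), data = d,
                    family = stats::poisson(),
                    offset = offset_log_effort),
        error = function(e) stop("GLMM failed for ", lab, ": ",
                                 conditionMessage(e))
      ),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
          stop("GLMM did not converge for ", lab, ": ", conditionMessage(w))
        }
        invokeRestart("muffleWarning")
      }
    )
    beta <- lme4::fixef(fit)[["x"]]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2]
  } else {
    warning("single protected area for ", lab,
            ": fitting fixed-effects Poisson regression")
    fit <- stats::glm(response_count ~ x, data = d, family = stats::poisson(),
                      offset = offset_log_effort)
    beta <- stats::coef(fit)[["x"]]
    se <- summary(fit)$coefficients["x", "Std. Error"]
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- beta + c(-1, 1) * z * se
  direction <- if (ci[1] > 0) "bottom_up" else if (ci[2] < 0) "top_down" else "none"
  data.frame(response_group = response_name, predictor_group = predictor_name,
             beta = beta, se = se, ci_lo = ci[1], ci_hi = ci[2],
             direction = direction,
             n_response = sum(pairs$response_count),
             n_predictor = sum(pairs$predictor_count),
             sites_used = n_area, row.names = NULL)
}

#' Pairwise coupling suite over guild x size groups
#'
#' Restricts the events to protected areas where large carnivores were
#' detected, builds sun-anchored hourly counts per guild x size group
#' (species above the 580 kg predation-risk threshold are excluded), and
#' fits [fit_coupling()] for every prey/subordinate group against large and
#' small carnivores. Pairs with too few events, or whose model does not
#' converge, are reported as skipped.
#'
#' @param events independent events joined to traits (see [join_traits()]).
#' @param min_events minimum independent events per group, default 25.
#' @param pairs group pairs, defaults to [default_group_pairs()].
#' @param ... passed to [fit_coupling()].
#' @return data.frame with one row per pair, including `skipped` and
#'   `reason` columns.
#' @export
run_pairwise_suite <- function(events, min_events = 25, pairs = NULL, ...) {
  if (is.null(pairs)) pairs <- default_group_pairs()
  keep_area <- unique(events$protected_area[
    events$guild == "carnivore" & events$size_class == "large"])
  ev <- events[events$protected_area %in% keep_area &
                 events$size_class != "excluded", , drop = FALSE]
  areas <- sort(unique(ev$protected_area))
  res <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    rn <- paste(p$resp_size, p$resp_guild)
    pn <- paste(p$pred_size, p$pred_guild)
    resp <- suppressWarnings(
      hourly_counts(ev, guild = p$resp_guild, size_class = p$resp_size,
                    areas = areas))
    pred <- suppressWarnings(
      hourly_counts(ev, guild = p$pred_guild, size_class = p$pred_size,
                    areas = areas))
    skip_row <- data.frame(response_group = rn, predictor_group = pn,
                           beta = NA_real_, se = NA_real_, ci_lo = NA_real_,
                           ci_hi = NA_real_, direction = NA_character_,
                           n_response = sum(resp), n_predictor = sum(pred),
                           sites_used = length(areas), skipped = TRUE,
                           reason = "insufficient events")
    if (sum(resp) < min_events || sum(pred) < min_events) {
      res[[i]] <- skip_row
      next
    }
    d <- data.frame(protected_area = rep(rownames(resp), 24),
                    anchored_hour = rep(0:23, each = nrow(resp)),
                    response_count = as.vector(resp),
                    predictor_count = as.vector(pred))
    row <- tryCatch({
      out <- fit_coupling(d, rn, pn, ...)
      out$skipped <- FALSE; out$reason <- ""
      out
    }, error = function(e) {
      skip_row$reason <- conditionMessage(e)
      skip_row
    })
    res[[i]] <- row
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
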