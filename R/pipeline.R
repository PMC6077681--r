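#' Default drill-condition grid
#'
#' The 12 study conditions: flexion 100-130 degrees in 10-degree steps
#' crossed with drill-angle offsets {0, -10, -20} degrees from the MTA.
#'
#' @return data.frame with columns `flexion_deg`, `offset_from_mta`.
#' @export
drill_conditions <- function() {
  expand.grid(flexion_deg = c(100, 110, 120, 130),
              offset_from_mta = c(0, -10, -20),
              KEEP.OUT.ATTRS = FALSE)
}

#' Run the full drilling experiment over a cohort
#'
#' For every subject and flexion angle: pose the knee, find the MTA,
#' derive the MTA-10 and MTA-20 portals by moving the drill laterally,
#' drill the virtual cylinder, classify wall breakage, and measure the
#' graft bending angle in the full-extension pose. Failures (e.g. an
#' unreachable target angle) are recorded per row with an error code and
#' never abort the batch. Fully deterministic given the cohort and
#' configuration.
#'
#' @param cohort list of `knee_model` objects.
#' @param conditions condition grid (default [drill_conditions()]).
#' @param diameter_mm drill diameter (default 8).
#' @param anterior_offset_mm portal-line AP offset (default 15).
#' @param breakage_opts options forwarded to [classify_breakage()].
#' @param verbose print per-subject progress to stderr.
#' @return long-format data.frame (`result_table`): one row per subject x
#'   condition with `subject_id`, `flexion_deg`, `offset_from_mta`,
#'   `mta_angle_deg`, `drill_angle_deg`, `length_mm`, `short`, `breakage`,
#'   `bending_angle_deg`, `error`.
#' @export
run_grid <- function(cohort, conditions = drill_conditions(), diameter_mm = 8,
                     anterior_offset_mm = 15, breakage_opts = list(),
                     verbose = FALSE) {
  stopifnot(length(cohort) >= 1)
  flexions <- sort(unique(conditions$flexion_deg))
  offsets <- sort(unique(conditions$offset_from_mta), decreasing = TRUE)
  rows <- list()
  for (i in seq_along(cohort)) {
    t0 <- proc.time()[["elapsed"]]
    model <- canonical_knee(cohort[[i]])
    lm_ok <- tryCatch(knee_landmarks(model), error = function(e) e)
    for (fx in flexions) {
      subject_rows <- lapply(offsets, function(off) {
        data.frame(subject_id = i, flexion_deg = fx, offset_from_mta = off,
                   mta_angle_deg = NA_real_, drill_angle_deg = NA_real_,
                   length_mm = NA_real_, short = NA, breakage = NA_character_,
                   bending_angle_deg = NA_real_, error = NA_character_)
      })
      names(subject_rows) <- as.character(offsets)
      if (inherits(lm_ok, "error")) {
        for (o in names(subject_rows))
          subject_rows[[o]]$error <- paste("landmarks:", conditionMessage(lm_ok))
      } else {
        lms <- lm_ok
        F <- lms$femoral_fp
        A <- lms$tibial_fp
        posed <- tryCatch(flex_knee(model, lms, fx), error = function(e) e)
        mta <- if (inherits(posed, "error")) posed else
          tryCatch(find_mta(posed, F, diameter_mm,
                            line = portal_line(posed, anterior_offset_mm)),
                   error = function(e) e)
        for (o in names(subject_rows)) {
          off <- as.numeric(o)
          if (inherits(mta, "error")) {
            subject_rows[[o]]$error <- paste("mta:", conditionMessage(mta))
            next
          }
          sol <- if (off == 0) mta else
            tryCatch(portal_at_angle(posed, F, mta$transverse_angle_deg + off,
                                     mta = mta),
                     error = function(e) e)
          if (inherits(sol, "error")) {
            subject_rows[[o]]$error <- paste("portal:", conditionMessage(sol))
            subject_rows[[o]]$mta_angle_deg <- mta$transverse_angle_deg
            next
          }
          tun <- tryCatch(drill_tunnel(model$femur, F, sol, diameter_mm,
                                       breakage_opts = breakage_opts),
                          error = function(e) e)
          if (inherits(tun, "error")) {
            subject_rows[[o]]$error <- paste("drill:", conditionMessage(tun))
            subject_rows[[o]]$mta_angle_deg <- mta$transverse_angle_deg
            next
          }
          bend <- graft_bending_angle(A, F, tun$exit_point)
          subject_rows[[o]] <- data.frame(
            subject_id = i, flexion_deg = fx, offset_from_mta = off,
            mta_angle_deg = mta$transverse_angle_deg,
            drill_angle_deg = sol$transverse_angle_deg,
            length_mm = tun$length_mm, short = tun$short,
            breakage = tun$breakage, bending_angle_deg = bend,
            error = NA_character_)
        }
      }
      rows <- c(rows, subject_rows)
    }
    if (verbose)
      message(sprintf("subject %d/%d done in %.1f s", i, length(cohort),
                      proc.time()[["elapsed"]] - t0))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("result_table", class(out))
  out
}

#' Summarize a result table into the study's per-condition tables
#'
#' @param results a `result_table` from [run_grid()].
#' @return list of data.frames keyed by condition cell (flexion x offset):
#'   `length_summary` and `bending_summary` (mean, sd with n-1 denominator,
#'   min, max, n), `short_proportions` (count, proportion),
#'   `breakage_proportions` (entrance `eb`, mid-tunnel `mb` and total `tb`
#'   counts and proportions, `tb = eb + mb`).
#' @export
summarize_results <- function(results) {
  ok <- results[is.na(results$error), , drop = FALSE]
  if (nrow(ok) < nrow(results))
    warning(sprintf("%d of %d rows failed and are summarized with reduced n",
                    nrow(results) - nrow(ok), nrow(results)))
  key <- list(flexion_deg = ok$flexion_deg, offset_from_mta = ok$offset_from_mta)
  num_summary <- function(x) {
    agg <- aggregate(x, key, function(v)
      c(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v),
        n = length(v)))
    cbind(agg[1:2], as.data.frame(agg$x))
  }
  prop_summary <- function(flag) {
    agg <- aggregate(flag, key, function(v) c(count = sum(v), n = length(v)))
    out <- cbind(agg[1:2], as.data.frame(agg$x))
    out$proportion <- out$count / out$n
    out
  }
  brk <- aggregate(cbind(eb = ok$breakage == "entrance",
                         mb = ok$breakage == "mid_tunnel"), key, sum)
  nn <- aggregate(ok$breakage, key, length)
  brk$tb <- brk$eb + brk$mb
  brk$n <- nn$x
  brk$eb_prop <- brk$eb / brk$n
  brk$mb_prop <- brk$mb / brk$n
  brk$tb_prop <- brk$tb / brk$n
  list(length_summary = num_summary(ok$length_mm),
       bending_summary = num_summary(ok$bending_angle_deg),
       short_proportions = prop_summary(ok$short),
       breakage_proportions = brk)
}

# subjects x levels matrix of `metric` with the other factor fixed
condition_matrix <- function(results, metric, family = c("flexion", "drill"),
                             fixed) {
  family <- match.arg(family)
  ok <- results[is.na(results$error), , drop = FALSE]
  sub <- if (family == "flexion") ok[ok$offset_from_mta == fixed, ] else
    ok[ok$flexion_deg == fixed, ]
  lev_col <- if (family == "flexion") "flexion_deg" else "offset_from_mta"
  levs <- sort(unique(sub[[lev_col]]))
  if (family == "drill") levs <- sort(levs, decreasing = TRUE)  # MTA first
  subjects <- sort(unique(sub$subject_id))
  m <- matrix(NA_real_, length(subjects), length(levs),
              dimnames = list(subjects, paste0(lev_col, "_", levs)))
  for (j in seq_along(levs)) {
    rows <- sub[sub[[lev_col]] == levs[j], ]
    m[match(rows$subject_id, subjects), j] <- rows[[metric]]
  }
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Statistical comparisons of a result table
#'
#' Reproduces the study's analysis families: repeated-measures ANOVA with
#' Bonferroni post hoc pairwise t tests for the continuous metrics (tunnel
#' length, bending angle) and Cochran's Q for the dichotomous ones (short
#' tunnel, any wall breakage), either across flexion angles at a fixed
#' drill offset or across drill offsets at a fixed flexion angle.
#'
#' @param results a `result_table`.
#' @param metric one of `"length_mm"`, `"bending_angle_deg"`, `"short"`,
#'   `"breakage"`.
#' @param family `"flexion"` (levels = flexion angles) or `"drill"`
#'   (levels = drill offsets).
#' @param fixed the fixed level of the other factor (an offset for the
#'   flexion family, a flexion angle for the drill family).
#' @return for continuous metrics, list with `omnibus` (`kd_test`) and
#'   `pairwise` (list of `kd_test`); for dichotomous metrics, a `kd_test`.
#' @export
compare_conditions <- function(results,
                               metric = c("length_mm", "bending_angle_deg",
                                          "short", "breakage"),
                               family = c("flexion", "drill"), fixed) {
  metric <- match.arg(metric)
  family <- match.arg(family)
  if (metric %in% c("length_mm", "bending_angle_deg")) {
    m <- condition_matrix(results, metric, family, fixed)
    list(omnibus = rm_anova(m), pairwise = bonferroni_pairs(m))
  } else {
    ok <- results
    ok$any_breakage <- as.numeric(!is.na(ok$breakage) & ok$breakage != "none")
    ok$short_num <- as.numeric(ok$short)
    col <- if (metric == "short") "short_num" else "any_breakage"
    m <- condition_matrix(ok, col, family, fixed)
    cochran_q(m)
  }
}

#' Render summary tables as Markdown
#'
#' Formats the per-condition summaries in the layout of the study tables:
#' flexion angles as rows, drill angles (MTA, MTA-10, MTA-20) as columns,
#' cells as `mean +/- sd (min~max)` for continuous metrics and
#' `count (percent)` for proportions.
#'
#' @param summaries output of [summarize_results()].
#' @return character vector of Markdown lines.
#' @export
report_markdown <- function(summaries) {
  cols <- c(0, -10, -20)
  col_names <- c("MTA", "MTA-10°", "MTA-20°")
  fmt_num <- function(df) {
    function(fx, off) {
      r <- df[df$flexion_deg == fx & df$offset_from_mta == off, ]
      if (nrow(r) == 0) return("-")
      sprintf("%.1f±%.1f (%.1f~%.1f)", r$mean, r$sd, r$min, r$max)
    }
  }
  fmt_prop <- function(df, cnt, prp) {
    function(fx, off) {
      r <- df[df$flexion_deg == fx & df$offset_from_mta == off, ]
      if (nrow(r) == 0) return("-")
      sprintf("%d (%.1f%%)", r[[cnt]], 100 * r[[prp]])
    }
  }
  render <- function(title, cell_fun) {
    fxs <- sort(unique(summaries$length_summary$flexion_deg))
    lines <- c(paste0("### ", title), "",
               paste0("| Flexion | ", paste(col_names, collapse = " | "), " |"),
               paste0("|---|", paste(rep("---", length(cols)), collapse = "|"), "|"))
    for (fx in fxs) {
      cells <- vapply(cols, function(off) cell_fun(fx, off), character(1))
      lines <- c(lines, paste0("| ", fx, "° | ",
                               paste(cells, collapse = " | "), " |"))
    }
    c(lines, "")
  }
  c(render("Femoral tunnel length (mm)", fmt_num(summaries$length_summary)),
    render("Graft bending angle (°)", fmt_num(summaries$bending_summary)),
    render("Short tunnels (<25 mm)",
           fmt_prop(summaries$short_proportions, "count", "proportion")),
    render("Wall breakage, total (EB + MB)",
           fmt_prop(summaries$breakage_proportions, "tb", "tb_prop")),
    render("Entrance breakage (EB)",
           fmt_prop(summaries$breakage_proportions, "eb", "eb_prop")),
    render("Mid-tunnel breakage (MB)",
           fmt_prop(summaries$breakage_proportions, "mb", "mb_prop")))
}
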