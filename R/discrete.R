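#' Descriptive statistics for discrete stride variables
#'
#' Mean and SD over strides pooled within limb role (and muscle, for sEMG
#' variables), per variable; the layout of the conventional summary tables.
#'
#' @param table Long data frame with columns `horse`, `lead`, `limb_role`,
#'   `stride`, `variable`, `value` (and optionally `muscle`).
#' @return Data frame: (`muscle`,) `variable`, `limb_role`, `n`, `mean`,
#'   `sd`.
#' @export
summarize_discrete <- function(table) {
  stopifnot(nrow(table) > 0,
            all(c("limb_role", "variable", "value") %in% names(table)))
  keys <- c(if ("muscle" %in% names(table)) "muscle", "variable", "limb_role")
  agg <- stats::aggregate(table$value,
                          by = lapply(keys, function(k)
                            ifelse(is.na(table[[k]]), "", table[[k]])),
                          FUN = function(v) c(n = sum(is.finite(v)),
                                              mean = mean(v, na.rm = TRUE),
                                              sd = stats::sd(v, na.rm = TRUE)))
  out <- data.frame(agg[, seq_along(keys), drop = FALSE],
                    n = agg$x[, "n"], mean = agg$x[, "mean"],
                    sd = agg$x[, "sd"])
  names(out)[seq_along(keys)] <- keys
  out$sd[out$n == 1] <- 0
  out[do.call(order, out[keys]), , drop = FALSE]
}

#' Within-subject comparison of a discrete variable between limb roles
#'
#' Linear mixed model fitted by REML with limb role as a fixed factor and a
#' random intercept per horse; the p-value uses the Satterthwaite
#' degrees-of-freedom approximation. On a balanced design collapsed to
#' horse means this reproduces the paired t-test.
#'
#' @param table Long data frame as in [summarize_discrete()].
#' @param variable Variable name to compare.
#' @param muscle Optional muscle filter.
#' @return List: `estimate` (second level minus first), `se`, `df`,
#'   `p_value`, `levels`, `n_horses`.
#' @export
compare_limbs <- function(table, variable, muscle = NULL) {
  d <- table[table$variable == variable, ]
  if (!is.null(muscle)) d <- d[d$muscle == muscle, ]
  d <- d[is.finite(d$value), ]
  lv <- sort(unique(d$limb_role))
  if (length(lv) != 2) stop("need exactly two limb roles, found: ",
                            paste(lv, collapse = ", "))
  both <- vapply(unique(d$horse), function(h)
    all(lv %in% d$limb_role[d$horse == h]), logical(1))
  if (sum(both) < 2)
    stop("mixed model unidentifiable: fewer than 2 horses with both limb roles")
  d <- d[d$horse %in% unique(d$horse)[both], ]
  d$limb_role <- factor(d$limb_role, levels = lv)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(value ~ limb_role + (1 | horse), data = d, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                                                 lme4::.makeCC("ignore", tol = 1e-4)))))
  co <- stats::coef(summary(fit))
  list(estimate = co[2, "Estimate"], se = co[2, "Std. Error"],
       df = co[2, "df"], p_value = co[2, "Pr(>|t|)"],
       levels = lv, n_horses = length(unique(d$horse)))
}

#' Composite-stride phasic activity diagram data
#'
#' Places leading- and trailing-limb stance and main-burst bars on one
#' composite stride referenced to the trailing-hind impact: leading-limb
#' data are shifted by `shift_ratio` times the mean TrH stance duration
#' (in % stride), the published advanced-placement ratio between TrH-LdH
#' impacts and TrH stance.
#'
#' @param bursts Data frame of mean main-burst windows: `muscle`,
#'   `limb_role`, `onset_pct`, `offset_pct`, and optionally `consistent`
#'   (fraction of strides with a main burst).
#' @param stances Data frame of mean stance windows: `limb_role`,
#'   `start_pct`, `end_pct` (stance start/end in % stride, unshifted).
#' @param trh_stance_pct Mean TrH stance duration in % stride.
#' @param shift_ratio Advanced placement / TrH stance ratio (default
#'   0.555).
#' @param consistent_min Fraction of strides above which a burst is drawn
#'   as consistent rather than intermittent (default 0.5).
#' @return List: `shift_pct` (the leading-limb shift = LdH impact position),
#'   `bars` (data frame of shifted bars with an `intermittent` flag).
#' @export
build_phasic_diagram <- function(bursts, stances, trh_stance_pct,
                                 shift_ratio = 0.555, consistent_min = 0.5) {
  shift <- shift_ratio * trh_stance_pct
  shift_of <- function(role) ifelse(grepl("^Ld", role), shift, 0)
  bars <- list()
  for (i in seq_len(nrow(stances))) {
    s <- stances[i, ]
    bars[[length(bars) + 1]] <- data.frame(
      element = "stance", muscle = NA_character_, limb_role = s$limb_role,
      start_pct = s$start_pct + shift_of(s$limb_role),
      end_pct = s$end_pct + shift_of(s$limb_role),
      intermittent = FALSE)
  }
  if (!is.null(bursts) && nrow(bursts) > 0) {
    cons <- bursts$consistent %||% rep(1, nrow(bursts))
    for (i in seq_len(nrow(bursts))) {
      b <- bursts[i, ]
      on <- ifelse(b$onset_pct >= 100, b$onset_pct - 100, b$onset_pct)
      bars[[length(bars) + 1]] <- data.frame(
        element = "burst", muscle = b$muscle, limb_role = b$limb_role,
        start_pct = on + shift_of(b$limb_role),
        end_pct = b$offset_pct + shift_of(b$limb_role),
        intermittent = cons[i] <= consistent_min)
    }
  }
  list(shift_pct = shift, bars = do.call(rbind, bars))
}
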