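# Septal spacing statistics: angle series, ontogenetic stage assignment,
# stage-point selection, one-way ANOVA across species/populations and
# Tukey-Kramer pairwise comparisons, and hatching detection.

#' Septal angles from cumulative rotational positions
#'
#' Successive differences of the septal rotational positions (degrees about
#' the coiling axis). The angle at position i separates septum i from septum
#' i + 1 and is associated with chamber i + 1; chamber 1 carries no angle.
#'
#' @param record a `specimen_record`, or a numeric vector of cumulative
#'   septal positions (degrees).
#' @return numeric vector of septal angles, degrees (length chambers - 1).
#' @export
septal_angles <- function(record) {
  pos <- if (inherits(record, "specimen_record")) record$septal_positions else as.numeric(record)
  d <- diff(pos)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("septal rotational positions must be finite and strictly increasing")
  d
}

#' Assign ontogenetic stages to chambers
#'
#' Three-stage rule: the last two chambers are `mature`; among the rest,
#' chambers with conch diameter < 30 mm are `pre_hatching` and chambers with
#' diameter >= 30 mm (up to the third chamber from the last) are
#' `juvenile_submature`. A chamber at exactly 30 mm is juvenile.
#'
#' @param record a `specimen_record`, or a named numeric vector of chamber
#'   diameters (mm) in chamber order.
#' @param pre_hatching_max_diameter stage boundary, mm.
#' @return data.frame with `chamber`, `diameter`, `stage`; attribute
#'   `rule_version`.
#' @export
assign_stage <- function(record, pre_hatching_max_diameter = 30) {
  if (inherits(record, "specimen_record")) {
    d <- unname(record$diameters_at_chamber)
    chamber <- 2:(length(d) + 1L)
  } else {
    d <- as.numeric(record)
    chamber <- seq_along(d)
  }
  if (length(d) < 4L) stop("stages are undefined for fewer than 4 chambers")
  stage <- ifelse(d < pre_hatching_max_diameter, "pre_hatching",
                  "juvenile_submature")
  stage[(length(d) - 1L):length(d)] <- "mature"
  out <- data.frame(chamber = chamber, diameter = d, stage = stage)
  attr(out, "rule_version") <- "v1"
  out
}

#' Select the two configurations closest to a target diameter
#'
#' Returns the indices of the two entries of `diameters` minimizing the
#' absolute difference from the target, ties broken toward the smaller
#' diameter. `target = "max"` (the maturity proxy) returns the last two
#' indices.
#'
#' @param diameters numeric vector of diameters in ontogenetic order (mm).
#' @param target numeric diameter (mm) or `"max"`.
#' @return integer vector of length 2, ordered by diameter.
#' @export
select_stage_points <- function(diameters, target) {
  d <- as.numeric(diameters)
  if (length(d) < 2L) stop("need at least 2 configurations")
  if (identical(target, "max")) return(c(length(d) - 1L, length(d)))
  ord <- order(abs(d - target), d)
  sort(ord[1:2])
}

#' One-way fixed-effects ANOVA
#'
#' Classical between/within decomposition via `anova(lm(...))`. When every
#' value in every group is identical the statistic is defined as F = 0 with
#' p = 1.
#'
#' @param groups named list mapping group label to numeric samples; at least
#'   two groups, at least one with two or more values.
#' @return object of class `conch_anova`: `F`, `df_between`, `df_within`,
#'   `p_value`, `group_means`, `group_ns`.
#' @export
anova_oneway <- function(groups) {
  groups <- groups[vapply(groups, length, 0L) > 0L]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  if (!any(vapply(groups, length, 0L) >= 2L))
    stop("need at least one group with 2 or more values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  df_b <- nlevels(g) - 1L
  df_w <- length(y) - nlevels(g)
  if (max(y) == min(y)) {
    Fst <- 0; p <- 1
  } else {
    a <- stats::anova(stats::lm(y ~ g))
    Fst <- a[["F value"]][1L]
    p <- a[["Pr(>F)"]][1L]
    if (!is.finite(Fst)) { Fst <- Inf; p <- 0 }
  }
  structure(list(F = Fst, df_between = df_b, df_within = df_w, p_value = p,
                 group_means = vapply(groups, mean, 0),
                 group_ns = vapply(groups, length, 0L)),
            class = "conch_anova")
}

#' @export
print.conch_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}

#' Tukey-Kramer pairwise comparisons
#'
#' Honestly-significant-difference comparisons of all group pairs
#' (studentized-range quantile with the Kramer correction for unbalanced
#' group sizes), via [stats::TukeyHSD()]. Groups with a single observation
#' are excluded with a warning.
#'
#' @param groups named list mapping group label to numeric samples.
#' @param alpha familywise significance level.
#' @return data.frame with `group_a`, `group_b`, `mean_difference`,
#'   `lower`, `upper`, `adjusted_p`, `significant`.
#' @export
pairwise_comparisons <- function(groups, alpha = 0.05) {
  small <- names(groups)[vapply(groups, length, 0L) < 2L]
  if (length(small)) {
    warning("excluding groups with n = 1 from pairwise tests: ",
            paste(small, collapse = ", "))
    groups <- groups[vapply(groups, length, 0L) >= 2L]
  }
  if (length(groups) < 2L) stop("need at least 2 groups with n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  tk <- stats::TukeyHSD(stats::aov(y ~ g), conf.level = 1 - alpha)$g
  pair <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  out <- data.frame(group_a = pair[, 2L], group_b = pair[, 1L],
                    mean_difference = tk[, "diff"],
                    lower = tk[, "lwr"], upper = tk[, "upr"],
                    adjusted_p = tk[, "p adj"],
                    significant = tk[, "p adj"] < alpha)
  rownames(out) <- NULL
  out
}

#' Detect the hatching chamber from a septal-angle series
#'
#' Hatching shows as a steep drop in septal spacing right after the
#' early-ontogeny maximum. Returns the chamber (numbering starts at 2; the
#' angle at series position i belongs to chamber i + 1) of the first angle
#' that falls at least `drop` relative to the running early maximum. `NA` if
#' no qualifying drop occurs within the first `search_chambers` chambers.
#'
#' @param angles numeric vector of septal angles (>= 10 values) or a
#'   `specimen_record`.
#' @param drop relative drop threshold (default 20 percent).
#' @param search_chambers how far into ontogeny to search.
#' @return integer chamber index, or `NA_integer_` when not detected.
#' @export
hatching_chamber <- function(angles, drop = 0.2, search_chambers = 12L) {
  if (inherits(angles, "specimen_record")) angles <- angles$septal_angles
  if (length(angles) < 10L) stop("need at least 10 septal angles")
  limit <- min(length(angles), search_chambers)
  runmax <- angles[1L]
  for (i in 2:limit) {
    if (angles[i] <= (1 - drop) * runmax) return(i + 1L)
    runmax <- max(runmax, angles[i])
  }
  NA_integer_
}

#' Stage-stratified septal-angle groups
#'
#' Pools each specimen's septal angles within an ontogenetic stage and groups
#' them by species/population label, the layout used for the stage ANOVAs.
#'
#' @param dataset a `conch_dataset`.
#' @param stage one of `"pre_hatching"`, `"juvenile_submature"`, `"mature"`.
#' @return named list of numeric vectors (one per species/population).
#' @export
stage_angle_groups <- function(dataset,
                               stage = c("pre_hatching", "juvenile_submature",
                                         "mature")) {
  stage <- match.arg(stage)
  groups <- list()
  for (r in dataset$specimens) {
    st <- assign_stage(r)
    a <- r$septal_angles[st$stage == stage]
    groups[[r$group]] <- c(groups[[r$group]], a)
  }
  groups
}
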