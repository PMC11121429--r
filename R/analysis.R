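# Cohort-level analysis designs: exclusions, variable roles, and the two
# hierarchical stepwise designs.

#' Variable roles of the analysis table
#'
#' Central declaration of which columns play which role:
#' `llvf` are the 12 usable low-level visual features (objective brightness
#' mean/SD are excluded as unreliable for ecological photographs),
#' `ratings` the 7 subjective view ratings, `controls` the 7 forced
#' sociodemographic confounders, `outcomes` the 2 behavioral outcomes.
#'
#' @param include_brightness Include `bright_mean`/`bright_sd` in `llvf`
#'   despite their unreliability flag.
#' @return Named list of character vectors.
#' @export
analysis_roles <- function(include_brightness = FALSE) {
  llvf <- feature_names()
  if (!include_brightness)
    llvf <- setdiff(llvf, c("bright_mean", "bright_sd"))
  list(llvf = llvf,
       ratings = c("pct_nature", "pct_manmade", "pct_sky", "quality",
                   "brightness_rating", "green_visibility",
                   "vegetation_rooms", "long_distance_view"),
       controls = c("age", "sex", "income", "time_home_pre",
                    "time_home_covid", "living_space", "image_count"),
       outcomes = c("negative_affect", "auc"))
}

#' Apply the cohort exclusion rules
#'
#' Removes the participant(s) with diverse sex (a factor level carried by a
#' single person would distort the models) and, when `outcome` columns are
#' named, performs listwise deletion on those columns for the respective
#' analysis.
#'
#' @param table Analysis table with a `sex` column (values `"male"`,
#'   `"female"`, `"diverse"`, or already-encoded numerics).
#' @param outcome Optional character vector of columns to require complete.
#' @return The filtered table; attributes `n_diverse_removed` and
#'   `n_missing_removed` record the bookkeeping.
#' @export
exclude_participants <- function(table, outcome = NULL) {
  stopifnot(is.data.frame(table))
  n0 <- nrow(table)
  if ("sex" %in% names(table) && !is.numeric(table$sex))
    table <- table[table$sex != "diverse", , drop = FALSE]
  n1 <- nrow(table)
  if (!is.null(outcome)) {
    miss <- setdiff(outcome, names(table))
    if (length(miss)) stop("unknown outcome columns: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    table <- table[complete.cases(table[, outcome, drop = FALSE]), ,
                   drop = FALSE]
  }
  attr(table, "n_diverse_removed") <- n0 - n1
  attr(table, "n_missing_removed") <- n1 - nrow(table)
  table
}

# After the diverse-sex exclusion, sex is a two-level variable; encode it as
# a binary indicator (female = 1, male = 0). Income is expected as the
# ordinal band index (1-7). Already-numeric columns pass through.
encode_analysis_table <- function(table) {
  if ("sex" %in% names(table) && !is.numeric(table$sex)) {
    lv <- unique(table$sex)
    if ("diverse" %in% lv)
      stop("encode after the diverse-sex exclusion", call. = FALSE)
    table$sex <- as.numeric(table$sex == "female")
  }
  table
}

#' Stepwise feature models for the three view ratings
#'
#' For each of the three criteria — perceived percentage of nature,
#' perceived percentage of man-made elements, and view quality — fits the
#' two-stage design: stage 1 is a bidirectional AIC-stepwise regression over
#' the 12 usable low-level visual features; stage 2 re-enters the stage-1
#' terms as a fixed block and lets the control variables compete stepwise,
#' probing the robustness of the feature model to sociodemographic
#' confounders.
#'
#' @param table Analysis table (one row per participant).
#' @param include_brightness Allow the objective-brightness features as
#'   candidates despite their unreliability flag.
#' @return Named list (one element per criterion) of lists with `stage1`
#'   and `stage2` [stepwise_lm()] fits.
#' @export
design_A_feature_models <- function(table, include_brightness = FALSE) {
  roles <- analysis_roles(include_brightness)
  out <- list()
  for (crit in c("pct_nature", "pct_manmade", "quality")) {
    tab <- encode_analysis_table(exclude_participants(table, crit))
    s1 <- stepwise_lm(tab, crit, candidates = roles$llvf)
    s2 <- stepwise_lm(tab, crit, candidates = roles$controls,
                      forced = s1$selected)
    out[[crit]] <- list(stage1 = s1, stage2 = s2)
  }
  out
}

#' Hierarchical stepwise models for the two behavioral outcomes
#'
#' For state negative affect and the delay-discounting AUC: block 1 enters
#' the seven control variables by forced entry (theoretically relevant
#' confounders are kept regardless of significance); block 2 selects among
#' the subjective view ratings and the 12 usable low-level visual features
#' by bidirectional AIC stepwise.
#'
#' @param table Analysis table.
#' @param include_brightness As in [design_A_feature_models()].
#' @return Named list (`negative_affect`, `auc`) of [stepwise_lm()] fits;
#'   each carries attributes `n_diverse_removed`/`n_missing_removed` from
#'   the exclusion step.
#' @export
design_B_outcome_models <- function(table, include_brightness = FALSE) {
  roles <- analysis_roles(include_brightness)
  ratings <- setdiff(roles$ratings, "pct_sky")
  out <- list()
  for (oc in roles$outcomes) {
    tab <- exclude_participants(table, oc)
    excl <- attributes(tab)[c("n_diverse_removed", "n_missing_removed")]
    tab <- encode_analysis_table(tab)
    fit <- stepwise_lm(tab, oc, candidates = c(ratings, roles$llvf),
                       forced = roles$controls)
    attr(fit, "n_diverse_removed") <- excl$n_diverse_removed
    attr(fit, "n_missing_removed") <- excl$n_missing_removed
    out[[oc]] <- fit
  }
  out
}
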