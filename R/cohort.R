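# Synthetic cohorts: participants, ratings, outcomes, choice logs.

#' Specify a synthetic cohort
#'
#' Defaults emulate the study population the package was built around:
#' 110 participants submitting on average 5.58 window photographs (SD 4.01,
#' minimum 1; truncated negative binomial), one participant of diverse sex,
#' demographic marginals drawn independently from the published bands, view
#' ratings generated from planted linear models on the true scene fractions
#' under a sum-100 constraint, state negative affect planted on the
#' brightness rating with a negative coefficient, and per-participant
#' hyperbolic discount rates driving the staircase choices.
#'
#' @param n_participants Cohort size.
#' @param img_mean,img_sd Moments of the image-count distribution before
#'   min-1 truncation (negative binomial).
#' @param width,height Scene size in pixels.
#' @param rating_coeffs Named list of the planted rating models:
#'   `pct_noise` (logistic-normal SD on the composition),
#'   `quality = c(intercept, b_green, b_sky, sd)`,
#'   `green_visibility = c(intercept, b_green, sd)`,
#'   `brightness = c(mean, sd)`, `long_distance = c(mean, sd)`.
#' @param outcome_coeffs Named list: `na = c(intercept, b_brightness, sd)`
#'   for the negative-affect model (the brightness-rating coefficient is
#'   negative by default: brighter homes, lower negative affect);
#'   `k_meanlog`, `k_sdlog` for the log-normal discount-rate distribution;
#'   `stadi_item_noise` (number of sum-preserving item perturbations per
#'   respondent).
#' @param missing_na,missing_auc Number of participants with injected
#'   missing negative-affect / choice-log data.
#' @param seed Master seed of the cohort.
#' @return Object of class `cohort_spec` (validated list).
#' @export
cohort_spec <- function(n_participants = 110L,
                        img_mean = 5.58, img_sd = 4.01,
                        width = 96L, height = 96L,
                        rating_coeffs = list(
                          pct_noise = 0.35,
                          quality = c(35, 45, 40, 15),
                          green_visibility = c(15, 75, 12),
                          brightness = c(65, 15),
                          long_distance = c(55, 20)),
                        outcome_coeffs = list(
                          na = c(58, -0.15, 6),
                          k_meanlog = log(0.02), k_sdlog = 1.2,
                          stadi_item_noise = 6L),
                        missing_na = 2L, missing_auc = 1L,
                        seed = 1L) {
  stopifnot(n_participants >= 3L, img_mean > 1, img_sd > 0,
            missing_na >= 0L, missing_auc >= 0L,
            missing_na + missing_auc + 1L < n_participants)
  structure(list(n_participants = as.integer(n_participants),
                 img_mean = img_mean, img_sd = img_sd,
                 width = as.integer(width), height = as.integer(height),
                 rating_coeffs = rating_coeffs,
                 outcome_coeffs = outcome_coeffs,
                 missing_na = as.integer(missing_na),
                 missing_auc = as.integer(missing_auc),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Largest-remainder rounding to a fixed integer total
#'
#' Rounds non-negative shares to integers that sum exactly to `total`:
#' floors are taken first and the remaining units go to the largest
#' fractional remainders (ties to the earliest entry).
#'
#' @param shares Non-negative numeric vector.
#' @param total Target integer sum (default 100).
#' @return Integer vector summing to `total`.
#' @export
largest_remainder <- function(shares, total = 100L) {
  stopifnot(all(shares >= 0), sum(shares) > 0)
  x <- shares / sum(shares) * total
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    give <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[give] <- fl[give] + 1
  }
  as.integer(fl)
}

#' Generate one participant's subjective view ratings
#'
#' The percentage composition (nature / man-made / sky) is drawn around the
#' true scene fractions by logistic-normal noise and converted to integers
#' by largest-remainder rounding, so the three always sum to exactly 100.
#' The remaining ratings come from planted linear models on the true
#' fractions, clipped to the 0-100 scales.
#'
#' @param truth Named fractions `sky`, `green`, `built` (from
#'   [generate_scene()]'s realized ground truth, averaged over the
#'   participant's windows).
#' @param coeffs Rating coefficients, see [cohort_spec()].
#' @param seed Integer seed.
#' @return One-row data frame of rating columns.
#' @export
generate_ratings <- function(truth, coeffs = cohort_spec()$rating_coeffs,
                             seed = 1L) {
  with_seed(seed, {
    p <- c(nature = unname(truth["green"]),
           manmade = max(0, 1 - truth["green"] - truth["sky"]),
           sky = unname(truth["sky"]))
    z <- log(p + 1e-8) + rnorm(3L, 0, coeffs$pct_noise)
    pct <- largest_remainder(exp(z - max(z)), 100L)
    clip100 <- function(x) pmin(pmax(x, 0), 100)
    q <- coeffs$quality
    gv <- coeffs$green_visibility
    data.frame(
      pct_nature = pct[1L], pct_manmade = pct[2L], pct_sky = pct[3L],
      quality = clip100(q[1L] + q[2L] * truth[["green"]] +
                          q[3L] * truth[["sky"]] + rnorm(1L, 0, q[4L])),
      brightness_rating = clip100(rnorm(1L, coeffs$brightness[1L],
                                        coeffs$brightness[2L])),
      green_visibility = clip100(gv[1L] + gv[2L] * truth[["green"]] +
                                   rnorm(1L, 0, gv[3L])),
      vegetation_rooms = rbinom(1L, 8L,
                                pmin(0.15 + 0.75 * truth[["green"]], 1)),
      long_distance_view = clip100(rnorm(1L, coeffs$long_distance[1L],
                                         coeffs$long_distance[2L])))
  })
}

#' Generate one participant's outcomes: inventory items and choice log
#'
#' The planted negative-affect composite is a linear function of the
#' brightness rating plus noise, clipped (with a warning) to the attainable
#' `[20, 80]`; the 20 state items are then constructed to reproduce that
#' composite exactly after euthymia reversal, with sum-preserving item
#' noise, and stored un-reversed. The choice log is produced by a
#' hyperbolic agent — choose the delayed reward iff
#' `100 / (1 + k * delay_days) >= offer` (ties go to delayed) — run through
#' the staircase for all 7 delays, six trials each, in randomized block
#' order.
#'
#' @param brightness_rating The participant's brightness rating (0-100).
#' @param k Hyperbolic discount rate (1/days).
#' @param coeffs Outcome coefficients, see [cohort_spec()].
#' @param seed Integer seed.
#' @return List: `stadi_items` (integer vector of 20 raw responses),
#'   `negative_affect` (the planted composite, equal to
#'   `score_stadi(stadi_items)`), `choices` (data frame `delay_label`,
#'   `trial_index`, `immediate_offer`, `choice`), `k`.
#' @export
generate_outcomes <- function(brightness_rating, k,
                              coeffs = cohort_spec()$outcome_coeffs,
                              seed = 1L) {
  with_seed(seed, {
    na_c <- coeffs$na
    target <- na_c[1L] + na_c[2L] * brightness_rating +
      rnorm(1L, 0, na_c[3L])
    if (target < 20 || target > 80) {
      warning("planted composite ", round(target, 1),
              " outside [20, 80]; clipped", call. = FALSE)
      target <- pmin(pmax(target, 20), 80)
    }
    items <- build_stadi_items(as.integer(round(target)),
                               coeffs$stadi_item_noise)
    delays <- discounting_delays()
    order_lbl <- sample(names(delays))
    logs <- lapply(order_lbl, function(lbl) {
      s <- staircase_init(delays[[lbl]])
      rows <- vector("list", 6L)
      for (t in 1:6) {
        sv <- 100 / (1 + k * delays[[lbl]])
        ch <- if (sv >= s$offer) "delayed" else "immediate"
        rows[[t]] <- data.frame(delay_label = lbl, trial_index = t,
                                immediate_offer = s$offer, choice = ch)
        s <- staircase_step(s, ch)
      }
      do.call(rbind, rows)
    })
    list(stadi_items = items,
         negative_affect = score_stadi(items),
         choices = do.call(rbind, logs), k = k)
  })
}

# Construct 20 raw item responses whose scored sum (euthymia reversed)
# equals `total`, then apply `n_noise` sum-preserving +1/-1 perturbations.
build_stadi_items <- function(total, n_noise = 0L) {
  stopifnot(total >= 20L, total <= 80L)
  scored <- rep(total %/% 20L, 20L)
  rem <- total %% 20L
  if (rem > 0L) {
    up <- sample.int(20L, rem)
    scored[up] <- scored[up] + 1L
  }
  for (i in seq_len(n_noise)) {
    can_up <- which(scored < 4L); can_dn <- which(scored > 1L)
    if (!length(can_up) || !length(can_dn)) break
    u <- can_up[sample.int(length(can_up), 1L)]
    d <- can_dn[sample.int(length(can_dn), 1L)]
    if (u == d) next
    scored[u] <- scored[u] + 1L; scored[d] <- scored[d] - 1L
  }
  items <- scored
  rev_idx <- stadi_facets() == "euthymia"
  items[rev_idx] <- 5L - items[rev_idx]
  as.integer(items)
}

#' Generate a full synthetic cohort on disk
#'
#' Writes the dataset tree consumed by the pipeline:
#' `out_dir/<participant_id>/window_<j>.png` plus
#' `window_<j>_skymask.png`, and `ratings.csv`, `demographics.csv`,
#' `stadi_items.csv`, `choices.csv`, `ground_truth.json` at the root.
#' Exactly one participant of diverse sex is injected (to exercise the
#' exclusion rule), as are `missing_na` participants without inventory
#' items and `missing_auc` without choice logs. All planted parameters and
#' per-participant ground truth are recorded in `ground_truth.json`.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `ground_truth`, and the four
#'   tables.
#' @export
generate_cohort <- function(spec = cohort_spec(), out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- spec$n_participants
  gt <- with_seed(spec$seed, draw_cohort_truth(spec))
  ratings <- list(); demo <- list(); stadi <- list(); choices <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("p%03d", i)
    pdir <- file.path(out_dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    pt <- gt$participants[[i]]
    realized <- matrix(0, length(pt$scene_seeds), 3L,
                       dimnames = list(NULL, c("sky", "green", "built")))
    for (j in seq_along(pt$scene_seeds)) {
      sc <- generate_scene(scene_spec(
        p_sky = pt$p_sky[j], sky_kind = pt$sky_kind,
        p_green = pt$p_green[j], built_density = pt$built_density,
        width = spec$width, height = spec$height,
        seed = pt$scene_seeds[j]))
      realized[j, ] <- sc$realized
      write_view_image(sc$image, file.path(pdir, sprintf("window_%d.png", j)))
      write_view_image(sc$masked,
                       file.path(pdir, sprintf("window_%d_skymask.png", j)))
    }
    truth <- colMeans(realized)
    gt$participants[[i]]$realized <- as.list(truth)
    r <- generate_ratings(truth, spec$rating_coeffs, seed = pt$rating_seed)
    ratings[[pid]] <- cbind(participant_id = pid, r)
    demo[[pid]] <- data.frame(
      participant_id = pid, age = pt$age, sex = pt$sex, income = pt$income,
      living_space = pt$living_space, time_home_pre = pt$time_home_pre,
      time_home_covid = pt$time_home_covid,
      image_count = length(pt$scene_seeds))
    oc <- generate_outcomes(r$brightness_rating, pt$k,
                            spec$outcome_coeffs, seed = pt$outcome_seed)
    gt$participants[[i]]$negative_affect <- oc$negative_affect
    if (!pt$missing_na)
      stadi[[pid]] <- data.frame(participant_id = pid,
                                 t(setNames(oc$stadi_items,
                                            paste0("item_", 1:20))))
    if (!pt$missing_auc)
      choices[[pid]] <- cbind(participant_id = pid, oc$choices)
  }
  tabs <- list(ratings = do.call(rbind, ratings),
               demographics = do.call(rbind, demo),
               stadi_items = do.call(rbind, stadi),
               choices = do.call(rbind, choices))
  for (nm in names(tabs)) {
    rownames(tabs[[nm]]) <- NULL
    write.csv(tabs[[nm]], file.path(out_dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  gt$spec <- unclass(spec)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(list(dir = out_dir, ground_truth = gt), tabs))
}

# Draw all per-participant latent parameters (RNG already seeded).
draw_cohort_truth <- function(spec) {
  n <- spec$n_participants
  img_counts <- integer(n)
  size <- spec$img_mean^2 / max(spec$img_sd^2 - spec$img_mean, 0.1)
  for (i in seq_len(n)) {
    repeat {
      x <- rnbinom(1L, size = size, mu = spec$img_mean)
      if (x >= 1L) { img_counts[i] <- x; break }
    }
  }
  diverse_idx <- sample.int(n, 1L)
  sex <- ifelse(runif(n) < 81 / 109, "female", "male")
  sex[diverse_idx] <- "diverse"
  eligible <- setdiff(seq_len(n), diverse_idx)
  miss_na <- sample(eligible, spec$missing_na)
  miss_auc <- sample(setdiff(eligible, miss_na), spec$missing_auc)
  income_p <- c(39, 16, 11, 24, 10, 5, 5) / 110
  participants <- vector("list", n)
  for (i in seq_len(n)) {
    base_sky <- rbeta(1L, 2.5, 6)
    base_green <- rbeta(1L, 2, 4)
    s <- base_sky + base_green
    if (s > 0.9) { base_sky <- base_sky * 0.9 / s
                   base_green <- base_green * 0.9 / s }
    m <- img_counts[i]
    p_sky <- pmin(pmax(base_sky + rnorm(m, 0, 0.03), 0), 0.95)
    p_green <- pmin(pmax(base_green + rnorm(m, 0, 0.04), 0), 0.95)
    over <- p_sky + p_green > 0.98
    p_green[over] <- 0.98 - p_sky[over]
    participants[[i]] <- list(
      id = sprintf("p%03d", i),
      age = round(pmin(pmax(rnorm(1L, 26.8, 7.99), 18), 70)),
      sex = sex[i],
      income = sample.int(7L, 1L, prob = income_p),
      living_space = round(rlnorm(1L, 4.007, 0.884), 1),
      time_home_pre = round(pmin(pmax(rnorm(1L, 14, 4), 2), 24), 1),
      time_home_covid = round(pmin(pmax(rnorm(1L, 20, 3), 4), 24), 1),
      k = rlnorm(1L, spec$outcome_coeffs$k_meanlog,
                 spec$outcome_coeffs$k_sdlog),
      sky_kind = sample(c("blue", "overcast"), 1L, prob = c(0.6, 0.4)),
      built_density = runif(1L, 0.2, 0.9),
      p_sky = p_sky, p_green = p_green,
      scene_seeds = sample.int(.Machine$integer.max - 1L, m),
      rating_seed = sample.int(.Machine$integer.max - 1L, 1L),
      outcome_seed = sample.int(.Machine$integer.max - 1L, 1L),
      missing_na = i %in% miss_na,
      missing_auc = i %in% miss_auc)
  }
  list(planted = list(rating_coeffs = spec$rating_coeffs,
                      outcome_coeffs = spec$outcome_coeffs),
       diverse_id = sprintf("p%03d", diverse_idx),
       missing_na_ids = sprintf("p%03d", miss_na),
       missing_auc_ids = sprintf("p%03d", miss_auc),
       participants = participants)
}
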