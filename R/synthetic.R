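# Synthetic diet-survey cohort generator. Emulates the structure of a
# multi-centre 4-day diary survey of preschool children: three age
# strata, ~92% dairy consumers with a right-skewed liquid-milk-equivalent
# distribution, subtype mix (liquid milk / milk powder / yogurt / other)
# shifting with age, zero-inflated dietary vitamin D, a heavy-tailed
# bimodal iodine mixture (a high-iodine household food), and ~41%
# dietary-supplement users. Fidelity targets are structural marginals
# (consumer share, median LME); per-nutrient medians are only required
# to be of plausible magnitude.

#' Specification of a synthetic cohort
#'
#' All defaults describe the emulated survey's structure; probabilities
#' are per age stratum (37--48, 49--60, 61--72 months).
#'
#' @param n_per_age_group Integer vector of stratum sizes.
#' @param dairy_consumer_prob Probability of consuming any dairy over the
#'   diary, per stratum.
#' @param subtype_probs 4 x 3 matrix of marginal consumption
#'   probabilities (rows `LIQUID_MILK`, `MILK_POWDER`, `YOGURT`,
#'   `OTHER_DAIRY`; columns the strata).
#' @param lme_quartiles Cohort-wide target quartiles of liquid milk
#'   equivalents, g/d: `c(p25, p50, p75)`.
#' @param supplement_user_prob Share of children taking a dietary
#'   supplement.
#' @param high_iodine_prob Share of households regularly serving a
#'   high-iodine food (drives the upper iodine mode).
#' @param fish_d_prob Share of children regularly eating a
#'   vitamin-D-rich fish (one of the few non-zero dietary D sources).
#' @param bg_energy_median,bg_energy_sdlog Lognormal parameters of the
#'   non-dairy background diet's daily energy (kcal/d).
#' @param n_background_foods Size of the generated non-dairy food pool.
#' @param foods_per_day Range of distinct background foods per diary day.
#' @param ref_milk_protein Reference milk protein used for LME
#'   round-trips, g/100 g.
#' @param seed Integer seed fixing the entire output stream.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_age_group = c(`37-48` = 224L, `49-60` = 226L, `61-72` = 226L),
                        dairy_consumer_prob = c(0.9375, 0.9241, 0.9152),
                        subtype_probs = rbind(
                          LIQUID_MILK = c(0.5446, 0.5973, 0.6283),
                          MILK_POWDER = c(0.5000, 0.4204, 0.3097),
                          YOGURT      = c(0.3393, 0.3584, 0.3496),
                          OTHER_DAIRY = c(0.1964, 0.1593, 0.1681)),
                        lme_quartiles = c(p25 = 84.61, p50 = 174.00, p75 = 255.70),
                        supplement_user_prob = 0.411,
                        high_iodine_prob = 0.30,
                        fish_d_prob = 0.10,
                        bg_energy_median = 880,
                        bg_energy_sdlog = 0.35,
                        n_background_foods = 60L,
                        foods_per_day = c(8L, 15L),
                        ref_milk_protein = 3.0,
                        seed = 1L) {
  spec <- list(n_per_age_group = as.integer(n_per_age_group),
               dairy_consumer_prob = dairy_consumer_prob,
               subtype_probs = subtype_probs,
               lme_quartiles = lme_quartiles,
               supplement_user_prob = supplement_user_prob,
               high_iodine_prob = high_iodine_prob,
               fish_d_prob = fish_d_prob,
               bg_energy_median = bg_energy_median,
               bg_energy_sdlog = bg_energy_sdlog,
               n_background_foods = as.integer(n_background_foods),
               foods_per_day = as.integer(foods_per_day),
               ref_milk_protein = ref_milk_protein,
               seed = as.integer(seed))
  probs <- c(spec$dairy_consumer_prob, spec$subtype_probs,
             spec$supplement_user_prob, spec$high_iodine_prob, spec$fish_d_prob)
  if (any(probs < 0) || any(probs > 1)) {
    stop("cohort_spec probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(spec$n_per_age_group <= 0L)) stop("stratum sizes must be positive", call. = FALSE)
  if (any(spec$subtype_probs > rep(spec$dairy_consumer_prob, each = 4))) {
    stop("subtype probabilities cannot exceed the dairy-consumer probability",
         call. = FALSE)
  }
  q <- spec$lme_quartiles
  if (!(q[1] > 0 && q[1] < q[2] && q[2] < q[3])) {
    stop("lme_quartiles must satisfy 0 < p25 < p50 < p75", call. = FALSE)
  }
  class(spec) <- "cohort_spec"
  spec
}

#' Calibrate a lognormal to a median and quartiles
#'
#' `mu = log(median)`; `sigma` minimises the squared error of the 25th
#' and 75th percentiles against the targets. For quartiles symmetric on
#' the log scale the fit is exact.
#'
#' @param median,p25,p75 Target quantiles, `0 < p25 < median < p75`.
#' @return Named numeric `c(mu, sigma)`.
#' @export
#' @examples
#' calibrate_lognormal(100, 50, 200)  # sigma = log(2)/qnorm(.75)
calibrate_lognormal <- function(median, p25, p75) {
  if (!(p25 > 0 && p25 < median && median < p75)) {
    stop("quantiles must satisfy 0 < p25 < median < p75", call. = FALSE)
  }
  mu <- log(median)
  z <- stats::qnorm(0.75)
  obj <- function(s) (exp(mu - z * s) - p25)^2 + (exp(mu + z * s) - p75)^2
  s0 <- (log(p75) - log(p25)) / (2 * z)
  fit <- stats::optimize(obj, interval = c(s0 / 10, s0 * 10), tol = 1e-10)
  c(mu = mu, sigma = fit$minimum)
}

# Lognormal for LME among consumers when the target quartiles are
# cohort-wide and a (1 - consumer_prob) point mass sits at zero. Target
# probabilities are moved to the consumer scale, the median is pinned
# exactly and sigma is the least-squares slope through the remaining
# log-quantiles.
.fit_lme_lognormal <- function(lme_quartiles, consumer_prob) {
  p <- c(0.25, 0.5, 0.75)
  alpha <- (p - (1 - consumer_prob)) / consumer_prob
  keep <- alpha > 0 & alpha < 1
  z <- unname(stats::qnorm(alpha[keep]))
  y <- unname(log(lme_quartiles[keep]))
  zm <- z[p[keep] == 0.5]
  ym <- y[p[keep] == 0.5]
  sigma <- sum((z - zm) * (y - ym)) / sum((z - zm)^2)
  c(mu = ym - zm * sigma, sigma = sigma)
}

# ---- generated food pool ----------------------------------------------

# per-100 g composition ranges by background food archetype; columns are
# min/max pairs for a subset of nutrients, everything else zero.
.ARCHETYPES <- list(
  grain     = list(n = 12, portion = c(30, 120),
                   rng = list(energy = c(110, 360), carbohydrate = c(22, 78),
                              protein = c(2, 10), fat = c(0.5, 2.5), fiber = c(0.4, 3),
                              calcium = c(5, 30), iron = c(0.5, 2.5), zinc = c(0.5, 2),
                              potassium = c(50, 150), vitamin_b1 = c(0.02, 0.15),
                              vitamin_b2 = c(0.02, 0.08), vitamin_b3 = c(0.5, 2.5),
                              vitamin_b6 = c(0.03, 0.12), vitamin_b9 = c(5, 25))),
  vegetable = list(n = 14, portion = c(30, 120),
                   rng = list(energy = c(15, 45), carbohydrate = c(2, 8),
                              protein = c(1, 3), fat = c(0.1, 0.5), fiber = c(0.8, 3),
                              calcium = c(20, 80), iron = c(0.5, 2), zinc = c(0.2, 0.8),
                              iodine = c(0, 3), potassium = c(120, 350),
                              vitamin_a = c(10, 300), vitamin_b1 = c(0.02, 0.08),
                              vitamin_b2 = c(0.02, 0.1), vitamin_b3 = c(0.3, 1),
                              vitamin_b6 = c(0.05, 0.2), vitamin_b9 = c(20, 120),
                              vitamin_c = c(8, 60))),
  fruit     = list(n = 8, portion = c(50, 150),
                   rng = list(energy = c(35, 70), carbohydrate = c(8, 18),
                              protein = c(0.3, 1.2), fat = c(0.1, 0.4), fiber = c(0.5, 2.5),
                              calcium = c(4, 25), iron = c(0.2, 0.8), zinc = c(0.1, 0.3),
                              potassium = c(100, 300), vitamin_a = c(2, 80),
                              vitamin_b1 = c(0.01, 0.05), vitamin_b2 = c(0.01, 0.05),
                              vitamin_b3 = c(0.2, 0.6), vitamin_b6 = c(0.03, 0.15),
                              vitamin_b9 = c(5, 30), vitamin_c = c(5, 60))),
  meat      = list(n = 8, portion = c(20, 80),
                   rng = list(energy = c(120, 280), carbohydrate = c(0, 2),
                              protein = c(13, 22), fat = c(4, 22), calcium = c(3, 15),
                              iron = c(1, 3.5), zinc = c(1.5, 4.5), iodine = c(0, 3),
                              potassium = c(150, 350), vitamin_a = c(5, 50),
                              vitamin_b1 = c(0.05, 0.6), vitamin_b2 = c(0.1, 0.25),
                              vitamin_b3 = c(3, 7), vitamin_b6 = c(0.15, 0.45),
                              vitamin_b9 = c(3, 15), vitamin_b12 = c(0.5, 2.5))),
  egg       = list(n = 2, portion = c(25, 60),
                   rng = list(energy = c(139, 160), carbohydrate = c(1, 3),
                              protein = c(11, 14), fat = c(9, 11), dha = c(60, 120),
                              calcium = c(40, 60), iron = c(1.5, 2.5), zinc = c(0.9, 1.3),
                              iodine = c(15, 30), potassium = c(110, 150),
                              vitamin_a = c(190, 280), vitamin_b1 = c(0.08, 0.12),
                              vitamin_b2 = c(0.25, 0.35), vitamin_b3 = c(0.1, 0.3),
                              vitamin_b6 = c(0.08, 0.15), vitamin_b9 = c(40, 80),
                              vitamin_b12 = c(0.8, 1.3))),
  fish      = list(n = 4, portion = c(15, 60),
                   rng = list(energy = c(95, 160), protein = c(15, 20), fat = c(2, 8),
                              dha = c(150, 600), calcium = c(20, 80), iron = c(0.5, 1.5),
                              zinc = c(0.5, 1.5), iodine = c(8, 40), potassium = c(200, 400),
                              vitamin_a = c(5, 30), vitamin_b2 = c(0.05, 0.15),
                              vitamin_b3 = c(1.5, 4), vitamin_b12 = c(1, 4))),
  legume    = list(n = 5, portion = c(10, 60),
                   rng = list(energy = c(100, 380), carbohydrate = c(15, 60),
                              protein = c(8, 35), fat = c(1, 16), fiber = c(2, 8),
                              calcium = c(50, 200), iron = c(2, 7), zinc = c(1, 4),
                              potassium = c(300, 900), vitamin_b1 = c(0.1, 0.5),
                              vitamin_b9 = c(50, 200))),
  oil       = list(n = 2, portion = c(3, 12),
                   rng = list(energy = c(860, 900), fat = c(95, 100))),
  snack     = list(n = 5, portion = c(10, 50),
                   rng = list(energy = c(380, 560), carbohydrate = c(45, 75),
                              protein = c(4, 9), fat = c(12, 30), fiber = c(0.3, 2),
                              calcium = c(10, 60), iron = c(0.5, 2.5), zinc = c(0.3, 1.2),
                              potassium = c(60, 200), vitamin_b1 = c(0.02, 0.1),
                              vitamin_b2 = c(0.02, 0.1), vitamin_b3 = c(0.5, 2)))
)

# Fixed special-food and dairy compositions (per 100 g as consumed;
# milk powder per 100 g powder). Values are plausible label-scale
# magnitudes, not survey data.
.FIXED_FOODS <- local({
  row <- function(food_id, name, subtype, ...) {
    data.frame(food_id = food_id, name = name, dairy_subtype = subtype,
               as.list(nutrient_vector(...)), stringsAsFactors = FALSE)
  }
  rbind(
    row("dairy_liquid_milk", "liquid milk", "LIQUID_MILK",
        energy = 62, carbohydrate = 4.8, protein = 3.0, fat = 3.4,
        calcium = 104, iron = 0.3, zinc = 0.42, iodine = 1.9, potassium = 109,
        vitamin_a = 24, vitamin_b1 = 0.03, vitamin_b2 = 0.14, vitamin_b3 = 0.1,
        vitamin_b6 = 0.04, vitamin_b9 = 5, vitamin_b12 = 0.4, vitamin_c = 1),
    row("dairy_milk_powder", "formula milk powder", "MILK_POWDER",
        energy = 480, carbohydrate = 55, protein = 19, fat = 21, fiber = 4,
        dha = 55, calcium = 700, iron = 7.5, zinc = 6.5, iodine = 90,
        potassium = 550, vitamin_a = 400, vitamin_b1 = 0.35, vitamin_b2 = 0.7,
        vitamin_b3 = 3, vitamin_b6 = 0.3, vitamin_b9 = 90, vitamin_b12 = 2.2,
        vitamin_c = 50, vitamin_d = 7),
    row("dairy_yogurt", "yogurt", "YOGURT",
        energy = 72, carbohydrate = 10, protein = 2.8, fat = 2.5,
        calcium = 110, zinc = 0.4, potassium = 140, vitamin_a = 15,
        vitamin_b2 = 0.15, vitamin_b12 = 0.3),
    row("dairy_cheese", "cheese", "OTHER_DAIRY",
        energy = 330, carbohydrate = 3.5, protein = 25, fat = 25,
        calcium = 730, zinc = 3, iodine = 15, potassium = 75,
        vitamin_a = 150, vitamin_b2 = 0.3, vitamin_b12 = 1),
    row("kelp", "kelp (high-iodine)", "NONE",
        energy = 30, carbohydrate = 3, protein = 1.5, fiber = 1.5,
        calcium = 150, iron = 1, iodine = 30000, potassium = 200),
    row("fatty_fish_d", "fatty fish (vitamin D source)", "NONE",
        energy = 150, protein = 18, fat = 8, dha = 700, calcium = 30,
        iodine = 20, potassium = 300, vitamin_b12 = 3, vitamin_d = 10)
  )
})

.generate_food_pool <- function(n_background_foods) {
  counts <- vapply(.ARCHETYPES, `[[`, numeric(1), "n")
  counts <- round(counts / sum(counts) * n_background_foods)
  counts[1] <- counts[1] + (n_background_foods - sum(counts))
  rows <- list()
  for (arch in names(.ARCHETYPES)) {
    a <- .ARCHETYPES[[arch]]
    k <- counts[[arch]]
    if (k <= 0) next
    m <- matrix(0, nrow = k, ncol = length(.NUTRIENTS),
                dimnames = list(NULL, .NUTRIENTS))
    for (nu in names(a$rng)) {
      m[, nu] <- stats::runif(k, a$rng[[nu]][1], a$rng[[nu]][2])
    }
    rows[[arch]] <- data.frame(
      food_id = sprintf("bg_%s_%02d", arch, seq_len(k)),
      name = sprintf("%s %d (generated)", arch, seq_len(k)),
      dairy_subtype = "NONE", m, stringsAsFactors = FALSE)
  }
  pool <- do.call(rbind, rows)
  rownames(pool) <- NULL
  list(pool = pool,
       portions = do.call(rbind, lapply(names(.ARCHETYPES), function(arch) {
         a <- .ARCHETYPES[[arch]]
         k <- counts[[arch]]
         if (k <= 0) return(NULL)
         data.frame(food_id = sprintf("bg_%s_%02d", arch, seq_len(k)),
                    p_min = a$portion[1], p_max = a$portion[2],
                    stringsAsFactors = FALSE)
       })))
}

#' Generate a synthetic survey cohort
#'
#' Produces a full, internally consistent input set for the pipeline:
#' children roster, 4-day diet diaries (2 working + 2 weekend days),
#' supplement records, a composition table covering every diary food,
#' and a truth record of the latent per-child values used in generation
#' (true LME, background energy, household flags). Byte-identical output
#' for a given spec and seed.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort` list: `children`, `diet`, `supplements`,
#'   `compositions`, `truth`, `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  set.seed(spec$seed)
  n_groups <- spec$n_per_age_group
  n <- sum(n_groups)
  grp <- rep(1:3, n_groups)
  age_lo <- c(37, 49, 61)[grp]
  children <- data.frame(
    child_id = sprintf("C%04d", seq_len(n)),
    age_months = age_lo + sample.int(12, n, replace = TRUE) - 1L,
    stringsAsFactors = FALSE)
  children <- as_children(children)

  # dairy consumption structure
  consumer <- stats::runif(n) < spec$dairy_consumer_prob[grp]
  subtypes <- rownames(spec$subtype_probs)
  target <- t(spec$subtype_probs) / spec$dairy_consumer_prob  # 3 x 4, conditional on consumer
  # every consumer must have >= 1 subtype; conditioning independent draws
  # on that event inflates marginals, so solve for base probabilities q
  # whose conditioned marginals equal the targets: q = t * (1 - prod(1-q))
  cond <- target
  for (g in 1:3) {
    if (spec$dairy_consumer_prob[g] == 0) {
      cond[g, ] <- 0
      next
    }
    q <- target[g, ]
    for (it in 1:100) {
      qn <- target[g, ] * (1 - prod(1 - q))
      if (max(abs(qn - q)) < 1e-12) break
      q <- qn
    }
    cond[g, ] <- q
  }
  sub_flags <- matrix(FALSE, n, 4, dimnames = list(children$child_id, subtypes))
  idx_consumer <- which(consumer)
  todo <- idx_consumer
  while (length(todo)) {
    draw <- matrix(stats::runif(length(todo) * 4), ncol = 4) <
      cond[grp[todo], , drop = FALSE]
    sub_flags[todo, ] <- draw
    todo <- todo[rowSums(draw) == 0L]  # every consumer has at least one subtype
  }

  # latent LME per consumer, cohort-wide quartiles as targets
  overall_pc <- sum(spec$dairy_consumer_prob * n_groups) / n
  lme_true <- numeric(n)
  m <- sum(consumer)
  if (m > 0) {
    ln <- .fit_lme_lognormal(spec$lme_quartiles, overall_pc)
    # quantile-balanced (Latin hypercube) draw: one value per probability
    # stratum of the calibrated lognormal, randomly perturbed and permuted.
    # Keeps the marginal distribution while pinning the sample quartiles
    # to the calibration targets far more tightly than an iid draw.
    u <- (sample.int(m) - stats::runif(m)) / m
    lme_true[consumer] <- stats::qlnorm(u, ln[["mu"]], ln[["sigma"]])
  }

  # split LME across consumed subtypes and days
  share <- matrix(0, n, 4, dimnames = dimnames(sub_flags))
  w <- matrix(stats::rgamma(n * 4, shape = 2), n, 4) * sub_flags
  rs <- rowSums(w)
  share[rs > 0, ] <- w[rs > 0, ] / rs[rs > 0]
  lme_by_subtype <- share * lme_true
  day_w <- matrix(stats::rgamma(n * 4, shape = 8), n, 4)
  day_w <- day_w / rowSums(day_w) * 4

  pool <- .generate_food_pool(spec$n_background_foods)
  compositions <- as_composition_table(rbind(.FIXED_FOODS, pool$pool))

  # dairy records: grams per record invert the LME conversion exactly
  dairy_food <- c(LIQUID_MILK = "dairy_liquid_milk", MILK_POWDER = "dairy_milk_powder",
                  YOGURT = "dairy_yogurt", OTHER_DAIRY = "dairy_cheese")
  g_per_lme <- vapply(subtypes, function(s) {
    if (s == "LIQUID_MILK") 1
    else spec$ref_milk_protein / compositions[dairy_food[[s]], "protein"]
  }, numeric(1))
  drec <- which(lme_by_subtype > 0, arr.ind = TRUE)
  dairy_records <- if (nrow(drec)) {
    data.frame(
      child_id = rep(children$child_id[drec[, 1]], each = 4),
      day = rep(1:4, nrow(drec)),
      food_id = rep(unname(dairy_food[subtypes[drec[, 2]]]), each = 4),
      amount = as.vector(t(day_w[drec[, 1], , drop = FALSE])) *
        rep(lme_by_subtype[drec] * g_per_lme[drec[, 2]], each = 4),
      stringsAsFactors = FALSE)
  } else NULL

  # background diet, scaled per day to the child's latent energy target
  bg_energy <- stats::rlnorm(n, log(spec$bg_energy_median), spec$bg_energy_sdlog)
  k_day <- matrix(sample(seq(spec$foods_per_day[1], spec$foods_per_day[2]),
                         n * 4, replace = TRUE), n, 4)
  total_k <- sum(k_day)
  child_of <- rep(rep(seq_len(n), 4), as.vector(k_day))        # column-major: day blocks
  day_of <- rep(rep(1:4, each = n), as.vector(k_day))
  food_i <- sample(nrow(pool$pool), total_k, replace = TRUE)
  pr <- pool$portions[match(pool$pool$food_id[food_i], pool$portions$food_id), ]
  amt <- stats::runif(total_k, pr$p_min, pr$p_max)
  rec_energy <- pool$pool$energy[food_i] * amt / 100
  key <- (child_of - 1) * 4 + day_of
  day_energy <- rowsum(rec_energy, key)
  target <- (bg_energy[child_of] * day_w[cbind(child_of, day_of)])
  scale <- target / day_energy[match(key, as.numeric(rownames(day_energy)))]
  bg_records <- data.frame(
    child_id = children$child_id[child_of],
    day = day_of,
    food_id = pool$pool$food_id[food_i],
    amount = amt * scale,
    stringsAsFactors = FALSE)

  # household special foods: high-iodine food and vitamin-D fish
  kelp_flag <- stats::runif(n) < spec$high_iodine_prob
  fish_flag <- stats::runif(n) < spec$fish_d_prob
  special <- function(flag, food_id, meanlog, sdlog) {
    ids <- which(flag)
    if (!length(ids)) return(NULL)
    data.frame(child_id = rep(children$child_id[ids], each = 4),
               day = rep(1:4, length(ids)),
               food_id = food_id,
               amount = stats::rlnorm(4 * length(ids), meanlog, sdlog),
               stringsAsFactors = FALSE)
  }
  kelp_records <- special(kelp_flag, "kelp", log(1.9), 0.25)
  fish_records <- special(fish_flag, "fatty_fish_d", log(30), 0.3)

  diet <- rbind(dairy_records, bg_records, kelp_records, fish_records)
  diet$day_type <- c("working", "working", "weekend", "weekend")[diet$day]
  diet <- diet[order(diet$child_id, diet$day, diet$food_id),
               c("child_id", "day", "day_type", "food_id", "amount")]
  rownames(diet) <- NULL
  diet <- as_diet_records(diet, compositions = compositions, strict = TRUE)

  # supplements: users take one product daily over the diary
  supp_user <- stats::runif(n) < spec$supplement_user_prob
  supp <- NULL
  ids <- which(supp_user)
  if (length(ids)) {
    m <- length(ids)
    prod <- matrix(0, m, length(.NUTRIENTS), dimnames = list(NULL, .NUTRIENTS))
    pick <- function(p, lo, hi) (stats::runif(m) < p) * stats::runif(m, lo, hi)
    prod[, "calcium"] <- pick(0.5, 50, 150)
    prod[, "vitamin_d"] <- pick(0.35, 2.5, 10)
    prod[, "vitamin_c"] <- pick(0.5, 20, 100)
    prod[, "iron"] <- pick(0.3, 2, 5)
    prod[, "zinc"] <- pick(0.3, 1.5, 5)
    prod[, "vitamin_a"] <- pick(0.3, 100, 300)
    prod[, "vitamin_b12"] <- pick(0.25, 0.5, 1.5)
    prod[, "dha"] <- pick(0.2, 30, 100)
    supp <- data.frame(child_id = rep(children$child_id[ids], each = 4),
                       day = rep(1:4, m),
                       prod[rep(seq_len(m), each = 4), , drop = FALSE],
                       stringsAsFactors = FALSE)
    supp <- as_supplement_records(supp)
  }

  truth <- data.frame(
    child_id = children$child_id,
    age_months = children$age_months,
    consumer = consumer,
    lme_true = lme_true,
    bg_energy = bg_energy,
    high_iodine = kelp_flag,
    fish_d = fish_flag,
    supplement_user = supp_user,
    stringsAsFactors = FALSE)
  truth <- cbind(truth, stats::setNames(as.data.frame(lme_by_subtype),
                                        paste0("lme_", tolower(subtypes))))

  structure(list(children = children, diet = diet, supplements = supp,
                 compositions = compositions, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$children), " children, ",
      nrow(x$diet), " diary records, seed ", x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the exact CSV formats consumed by the loaders plus a JSON truth
#' file: `children.csv`, `diet_records.csv`, `supplement_records.csv`,
#' `composition_table.csv`, `truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    children = file.path(dir, "children.csv"),
    diet = file.path(dir, "diet_records.csv"),
    supplements = file.path(dir, "supplement_records.csv"),
    compositions = file.path(dir, "composition_table.csv"),
    truth = file.path(dir, "truth.json"))
  utils::write.csv(as.data.frame(cohort$children[, c("child_id", "age_months")]),
                   paths["children"], row.names = FALSE, fileEncoding = "UTF-8")
  write_diet_records(cohort$diet, paths["diet"])
  supp <- if (is.null(cohort$supplements)) {
    as.data.frame(stats::setNames(
      c(list(character(0), integer(0)), rep(list(numeric(0)), length(.NUTRIENTS))),
      c("child_id", "day", .NUTRIENTS)))
  } else as.data.frame(cohort$supplements)
  utils::write.csv(supp, paths["supplements"], row.names = FALSE, fileEncoding = "UTF-8")
  write_composition_table(cohort$compositions, paths["compositions"])
  jsonlite::write_json(cohort$truth, paths["truth"], dataframe = "rows", digits = NA)
  invisible(paths)
}
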