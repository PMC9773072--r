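# Domain types, loaders and validation.

test_that("nutrient_vector builds complete validated vectors", {
  v <- nutrient_vector(energy = 54, protein = 3.0)
  expect_length(v, 20)
  expect_identical(names(v), nutrients())
  expect_equal(v[["protein"]], 3.0)
  expect_equal(sum(v), 57)
  expect_error(nutrient_vector(proteine = 3), "unknown nutrient")
  expect_error(nutrient_vector(energy = -1), "negative")
  expect_error(validate_nutrient_vector(c(energy = 1)), "missing")
})

test_that("nutrient vector algebra is exact componentwise on rational fixtures", {
  set.seed(11)
  for (i in 1:20) {
    # rational values (k/8) keep float arithmetic exact
    a <- nutrient_vector(stats::setNames(sample(0:80, 20) / 8, nutrients()))
    b <- nutrient_vector(stats::setNames(sample(0:80, 20) / 8, nutrients()))
    cc <- nutrient_vector(stats::setNames(sample(0:80, 20) / 8, nutrients()))
    s <- sample(1:16, 1) / 4
    expect_identical((a + b) + cc, a + (b + cc))
    expect_identical(s * (a + b), s * a + s * b)
  }
})

test_that("composition table round-trips through CSV and validates schema", {
  comp <- tiny_compositions()
  expect_equal(composition_entry(comp, "milk_liq")$per100g[["protein"]], 3.0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_composition_table(comp, path)
  back <- load_composition_table(path)
  expect_equal(as.data.frame(back), as.data.frame(comp))

  df <- as.data.frame(comp)
  expect_error(as_composition_table(df[, setdiff(names(df), "vitamin_d")]),
               "vitamin_d")
  df2 <- df; df2$calcium[2] <- -1
  expect_error(as_composition_table(df2), "negative value.*calcium.*row 2")
  df3 <- df; df3$dairy_subtype[1] <- "CREAM"
  expect_error(as_composition_table(df3), "unknown dairy_subtype.*CREAM")
  expect_error(composition_entry(comp, "nope"), "unknown food_id")
})

test_that("a composition file with 323 foods yields a lookup of size 323", {
  base <- as.data.frame(tiny_compositions())[1, ]
  many <- base[rep(1, 323), ]
  many$food_id <- sprintf("f%03d", 1:323)
  comp <- as_composition_table(many)
  expect_equal(nrow(comp), 323)
  expect_equal(composition_entry(comp, "f200")$food_id, "f200")
})

test_that("diet record validation enforces the 2+2 four-day diary", {
  ok <- data.frame(child_id = "c1", day = 1:4,
                   day_type = c("working", "working", "weekend", "weekend"),
                   food_id = "rice", amount = 100)
  expect_s3_class(as_diet_records(ok), "diet_records")
  short <- ok[1:3, ]
  expect_error(as_diet_records(short), "c1.*days 1\\.\\.4")
  expect_s3_class(as_diet_records(short, strict = FALSE), "diet_records")
  imbalanced <- ok; imbalanced$day_type <- c("working", "working", "working", "weekend")
  expect_error(as_diet_records(imbalanced), "2 working and 2 weekend")
  bad_day <- ok; bad_day$day <- c(1, 2, 3, 5)
  expect_error(as_diet_records(bad_day), "1\\.\\.4")
  expect_error(as_diet_records(ok, compositions = tiny_compositions()[1:2, ]),
               "unknown food_id")
  neg <- ok; neg$amount[1] <- -5
  expect_error(as_diet_records(neg), "non-negative")
})

test_that("diary CSVs round-trip and group 676 children into 676 diaries", {
  n <- 676
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(child_id = sprintf("c%03d", i), day = 1:4,
               day_type = c("working", "working", "weekend", "weekend"),
               food_id = "rice", amount = 100 + i)
  }))
  rec <- as_diet_records(df)
  expect_equal(length(unique(rec$child_id)), 676)
  path <- withr::local_tempfile(fileext = ".csv")
  write_diet_records(rec, path)
  back <- load_diet_records(path)
  expect_equal(as.data.frame(back)[order(back$child_id, back$day), ],
               as.data.frame(rec)[order(rec$child_id, rec$day), ],
               ignore_attr = TRUE)
})

test_that("supplement records default missing nutrients to zero and reject negatives", {
  s <- as_supplement_records(data.frame(child_id = "c1", day = 1, vitamin_d = 5))
  expect_equal(s$vitamin_d, 5)
  expect_equal(s$calcium, 0)
  expect_error(as_supplement_records(data.frame(child_id = "c1", day = 1, iron = -1)),
               "negative")
  expect_error(as_supplement_records(data.frame(child_id = "c1", day = 1, foo = 1)),
               "unknown column")
})

test_that("DRI table validates rule structure, bands and lookups", {
  dri <- tiny_dri()
  r <- dri_lookup(dri, "calcium", 40)
  expect_equal(r$threshold, 600)
  expect_equal(r$rule_type, "EAR")
  expect_null(dri_lookup(dri, "fat_energy_pct", 40))

  overlapping <- data.frame(
    nutrient = "calcium", age_min_months = c(36, 48), age_max_months = c(60, 72),
    rule_type = "EAR", threshold = c(600, 650))
  expect_error(as_dri_table(overlapping), "overlapping age bands.*calcium")
  expect_error(as_dri_table(transform(as.data.frame(dri),
                                      nutrient = sub("calcium", "unobtainium", nutrient))),
               "unknown nutrient")
  fd <- as_dri_table(data.frame(nutrient = "fiber_density", age_min_months = 37,
                                age_max_months = 73, rule_type = "FIBER_DENSITY",
                                threshold = 10))
  expect_equal(dri_lookup(fd, "fiber_density", 50)$threshold, 10)
})

test_that("DRI config files load from JSON and YAML identically", {
  dri <- load_dri_table(dairysim_extdata("dri"))
  expect_s3_class(dri, "dri_table")
  # every in-range age resolves to exactly one rule per full-band nutrient
  for (nu in setdiff(unique(dri$nutrient), "fat_energy_pct")) {
    for (age in c(37, 48, 49, 60, 61, 72)) {
      expect_false(is.null(dri_lookup(dri, nu, age)))
    }
  }
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(seq_len(nrow(dri)), function(i) as.list(as.data.frame(dri)[i, ])),
                   ypath)
  expect_equal(as.data.frame(load_dri_table(ypath)), as.data.frame(dri))
})

test_that("age groups follow the half-open month bands", {
  expect_equal(as.character(age_group_of(c(37, 48, 49, 60, 61, 72))),
               c("37-48", "37-48", "49-60", "49-60", "61-72", "61-72"))
  expect_error(age_group_of(36), "37")
  expect_error(age_group_of(73), "37")
})
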