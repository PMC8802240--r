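rec <- function(loc = NA, bri = NA, ant = NA, sty = NA, sp = "s1") {
  data.frame(species = sp, sperm_location = loc, bristle_state = bri,
             antrum_state = ant, stylet_sharpness = sty,
             stringsAsFactors = FALSE)
}

test_that("syndrome classifier applies the decision rules in order", {
  # exclusively hypodermic sperm is decisive regardless of morphology
  r <- classify_syndrome(rec(loc = "hypodermic", bri = "present",
                             ant = "thickened", sty = "blunt"))
  expect_equal(r$syndrome, "hypodermic")
  expect_equal(r$rule, 1L)

  # hypodermic morphology without sperm observations
  r <- classify_syndrome(rec(bri = "reduced", ant = "simple", sty = "sharp"))
  expect_equal(r$syndrome, "hypodermic")
  expect_equal(r$rule, 2L)

  # sperm in both locations -> intermediate
  r <- classify_syndrome(rec(loc = "both", bri = "reduced",
                             ant = "thickened", sty = "sharp"))
  expect_equal(r$syndrome, "intermediate")
  expect_equal(r$rule, 3L)

  # antrum sperm + blunt stylet -> reciprocal, any bristle state
  r <- classify_syndrome(rec(loc = "antrum", bri = "absent", sty = "blunt"))
  expect_equal(r$syndrome, "reciprocal")
  expect_equal(r$rule, 4L)

  # antrum sperm + sharp stylet needs bristles for reciprocal
  r <- classify_syndrome(rec(loc = "antrum", bri = "present", sty = "sharp"))
  expect_equal(r$syndrome, "reciprocal")
  expect_equal(r$rule, 5L)

  # other combinations stay unclear
  r <- classify_syndrome(rec(bri = "present", ant = "thickened",
                             sty = "sharp"))
  expect_equal(r$syndrome, "unclear")
  expect_equal(r$rule, 6L)

  # neutral stylet counts as blunt-like for the reciprocal rule
  r <- classify_syndrome(rec(loc = "antrum", sty = "neutral"))
  expect_equal(r$syndrome, "reciprocal")
  expect_equal(r$rule, 4L)
})

test_that("classifier is total and deterministic over all input patterns", {
  vocab <- trait_vocabulary()
  grid <- expand.grid(
    loc = c(vocab$sperm_location, NA),
    bri = c(vocab$bristle_state, NA),
    ant = c(vocab$antrum_state, NA),
    sty = c(vocab$stylet_sharpness, NA),
    stringsAsFactors = FALSE)
  records <- data.frame(species = paste0("s", seq_len(nrow(grid))),
                        sperm_location = grid$loc,
                        bristle_state = grid$bri,
                        antrum_state = grid$ant,
                        stylet_sharpness = grid$sty,
                        stringsAsFactors = FALSE)
  out1 <- classify_syndrome(records)
  out2 <- classify_syndrome(records)
  expect_identical(out1, out2)
  expect_true(all(out1$syndrome %in%
                    c("hypodermic", "intermediate", "reciprocal",
                      "unclear")))
  expect_equal(nrow(out1), nrow(records))
  # rule id consistent with the assigned label
  lab_by_rule <- c("hypodermic", "hypodermic", "intermediate", "reciprocal",
                   "reciprocal", "unclear")
  expect_equal(out1$syndrome, lab_by_rule[out1$rule])
})

test_that("binary recoding follows the 0 = hypodermic-like convention", {
  expect_equal(recode_binary(c("hypodermic", "both", "antrum"),
                             "sperm_location"), c(0L, 0L, 1L))
  expect_equal(recode_binary(c("absent", "reduced", "present"),
                             "bristle_state"), c(0L, 0L, 1L))
  expect_equal(recode_binary(c("simple", "thickened"), "antrum_state"),
               c(0L, 1L))
  expect_equal(recode_binary(c("hypodermic", "intermediate", "reciprocal",
                               "unclear"), "syndrome"),
               c(0L, 0L, 1L, NA))
  expect_true(is.na(recode_binary(NA_character_, "bristle_state")))
  expect_true(is.na(recode_binary("both", "sperm_location",
                                  both_as = "exclude")))
  expect_error(recode_binary("spiky", "bristle_state"), "spiky")
})

test_that("binary recoding of the classifier output commutes with the
          trinary collapse", {
  vocab <- trait_vocabulary()
  set.seed(11)
  n <- 300
  records <- data.frame(
    species = paste0("s", 1:n),
    sperm_location = sample(c(vocab$sperm_location, NA), n, TRUE),
    bristle_state = sample(c(vocab$bristle_state, NA), n, TRUE),
    antrum_state = sample(c(vocab$antrum_state, NA), n, TRUE),
    stylet_sharpness = sample(c(vocab$stylet_sharpness, NA), n, TRUE),
    stringsAsFactors = FALSE)
  syn <- classify_syndrome(records)$syndrome
  bin_direct <- recode_binary(syn, "syndrome")
  tri <- recode_trinary(syn, "syndrome")
  bin_via_tri <- ifelse(is.na(tri), NA_integer_,
                        ifelse(tri == 2L, 1L, 0L))
  expect_identical(bin_direct, bin_via_tri)
})

test_that("quantitative transforms: sqrt-log for areas, log for lengths,
          mean of logs per species", {
  sp <- data.frame(
    species = c("a", "a", "a", "b"),
    trait = c("body_area", "sperm_length", "sperm_length", "sperm_length"),
    value = c(100, 10, 1000, 100))
  out <- transform_quantitative(sp)
  expect_equal(out$values["a", "body_area"], 1)
  expect_equal(out$values["b", "sperm_length"], 2)
  expect_equal(out$values["a", "sperm_length"], 2)  # mean(log10(10,1000))
  expect_equal(out$n["a", "sperm_length"], 2L)
  # mean-then-log alternative differs for skewed specimens
  alt <- transform_quantitative(sp, log_first = FALSE)
  expect_equal(alt$values["a", "sperm_length"], log10(505))
  expect_gt(alt$values["a", "sperm_length"], out$values["a", "sperm_length"])
})

test_that("non-positive measurements are rejected with the specimen named", {
  sp <- data.frame(species = c("a", "b"), trait = "sperm_length",
                   value = c(10, -1))
  expect_error(transform_quantitative(sp), "b")
})

test_that("trait table loader validates the controlled vocabulary", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(species = c("s1", "s2"),
                       sperm_location = c("hypodermic", "everywhere")),
            f, row.names = FALSE)
  expect_error(load_trait_table(f), "everywhere")
  write.csv(data.frame(species = c("s1", "s2"),
                       sperm_location = c("hypodermic", "")),
            f, row.names = FALSE)
  tab <- load_trait_table(f)
  expect_true(is.na(tab$sperm_location[2]))
  unlink(f)
})
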