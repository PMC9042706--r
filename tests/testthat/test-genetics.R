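variants <- function() read_variant_table(extfile("variants.tsv"))

test_that("the variant filter applies the effect, depth and frequency rules", {
  v <- variants()
  kept <- filter_variants(v)
  expect_setequal(kept$gene, c("MYD88", "EZH2", "KLHL6"))
  # BRAF dropped: 15 reads < 20 despite relevance
  expect_false("BRAF" %in% kept$gene)
  # TP53 dropped: common and not lymphoma-relevant; EZH2 kept: waived
  expect_false("TP53" %in% kept$gene)
  # NOTCH2 dropped: synonymous effect class
  expect_false("NOTCH2" %in% kept$gene)

  # rescuing the relevance flag keeps a common variant
  v2 <- v
  v2$lymphoma_relevant[v2$gene == "TP53"] <- TRUE
  expect_true("TP53" %in% filter_variants(v2)$gene)

  # idempotent
  expect_identical(filter_variants(kept), kept)

  v3 <- v
  v3$reads[2] <- NA
  expect_error(filter_variants(v3), "missing values")
  expect_error(filter_variants(v[, -3]), "lack fields")
})

test_that("marker integration rescues undetermined calls per the rules", {
  ann <- as_sample_annotation(data.frame(
    sample_id = paste0("s", 1:5),
    label = c("FL", "LPL/WM", "HCL", "FL", "MZL"),
    IGH_BCL2 = c("negative", "negative", "negative", "positive", "negative"),
    MYD88_L265P = c("negative", "positive", "negative", "negative",
                    "negative"),
    BRAF_V600E = c("negative", "negative", "positive", "negative",
                   "negative"),
    EZH2_Y646 = "negative",
    stringsAsFactors = FALSE))
  calls <- c("FL", "undetermined", "undetermined", "undetermined", "MZL")
  out <- integrate_markers(calls, ann)
  expect_equal(as.character(out),
               c("FL", "LPL/WM", "HCL", "FL", "MZL"))
  expect_equal(attr(out, "revised"), c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("only BRAF overrides a committed call; conflicts warn by priority", {
  ann <- as_sample_annotation(data.frame(
    sample_id = paste0("s", 1:3),
    label = c("MZL", "CLL/SLL", "MZL"),
    IGH_BCL2 = c("positive", "negative", "positive"),
    MYD88_L265P = c("negative", "negative", "positive"),
    BRAF_V600E = c("negative", "positive", "negative"),
    EZH2_Y646 = "negative",
    stringsAsFactors = FALSE))
  calls <- c("MZL", "CLL/SLL", "undetermined")
  expect_warning(out <- integrate_markers(calls, ann), "multiple positive")
  # IGH-BCL2 may not override the committed MZL call
  expect_equal(as.character(out)[1], "MZL")
  # BRAF always overrides: HCL sits outside the expression model
  expect_equal(as.character(out)[2], "HCL")
  # conflict resolved by priority MYD88 > IGH-BCL2
  expect_equal(as.character(out)[3], "LPL/WM")
})

test_that("integration is the identity when markers are unknown", {
  ann <- as_sample_annotation(data.frame(
    sample_id = paste0("s", 1:4),
    label = c("FL", "MZL", "control", "cMCL"),
    stringsAsFactors = FALSE))  # no marker columns -> all unknown
  calls <- c("FL", "undetermined", "undetermined", "cMCL")
  out <- integrate_markers(calls, ann)
  expect_equal(as.character(out), calls)
  expect_false(any(attr(out, "revised")))
})

test_that("correct calls are never corrupted under default precedence", {
  set.seed(51)
  n <- 60
  truth <- sample(c(SBCLN_ENTITIES, "HCL"), n, replace = TRUE)
  calls <- truth
  calls[sample(n, 20)] <- "undetermined"
  ann <- as_sample_annotation(data.frame(
    sample_id = paste0("s", seq_len(n)),
    label = truth,
    IGH_BCL2 = sample(c("positive", "negative"), n, TRUE),
    MYD88_L265P = sample(c("positive", "negative"), n, TRUE),
    BRAF_V600E = "negative",   # keep the always-override rule quiet
    EZH2_Y646 = sample(c("positive", "negative"), n, TRUE),
    stringsAsFactors = FALSE))
  out <- suppressWarnings(integrate_markers(calls, ann))
  was_correct <- calls == truth & calls != "undetermined"
  expect_true(all(as.character(out)[was_correct] == truth[was_correct]))
})

test_that("combined markers are admitted only on >=2 correct rescues", {
  rules <- integration_rules()
  ann <- as_sample_annotation(data.frame(
    sample_id = paste0("s", 1:6),
    label = c("FL", "FL", "LPL/WM", "FL", "MZL", "HCL"),
    IGH_BCL2 = c("positive", "positive", "negative", "negative",
                 "negative", "negative"),
    MYD88_L265P = c("negative", "negative", "positive", "negative",
                    "negative", "negative"),
    BRAF_V600E = "negative",
    EZH2_Y646 = "negative",
    stringsAsFactors = FALSE))
  truth <- ann$label
  calls <- c("undetermined", "undetermined", "undetermined",
             "FL", "MZL", "undetermined")
  adm <- select_combined_markers(rules, calls, truth, ann)
  # IGH-BCL2 rescues two FL cases -> admitted; MYD88 rescues one -> not;
  # BRAF matches nothing -> not
  expect_equal(adm$marker, "IGH_BCL2")
  expect_equal(adm$n_rescued, 2L)
})
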