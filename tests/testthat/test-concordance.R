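## Hand-built partitions over a fixed cast of specimens:
## STUDY: m1 = {s1, s2}, m2 = {s3}, m3 = {s4, s5}
## EXTERNAL: e1 (m1), e2 (m4)
cast_records <- function() {
  make_records(c("s1", "s2", "s3", "s4", "s5", "e1", "e2"),
               c("M one", "M one", "M two", "M three", "M three",
                 "M one", "M four"),
               provenance = c(rep("STUDY", 5), "EXTERNAL", "EXTERNAL"))
}

pt <- function(..., method = "m") partition(c(...), method)

test_that("split status counts occupied groups per method", {
  rec <- cast_records()
  parts <- list(a = pt(s1 = "g1", s2 = "g1", s3 = "g2", method = "a"),
                b = pt(s1 = "g1", s2 = "g2", s3 = "g3", method = "b"),
                c = pt(s3 = "g1", method = "c"))
  st <- split_status("M one", parts, rec)
  expect_identical(unname(st), c(FALSE, TRUE, NA))
  expect_false(split_status("M two", parts["a"], rec)[["a"]])
})

test_that("lump partners lists co-grouped morphospecies per method", {
  rec <- cast_records()
  parts <- list(a = pt(s1 = "g1", s3 = "g1", s4 = "g2", method = "a"),
                b = pt(s1 = "g1", s3 = "g2", s4 = "g2", s5 = "g2", method = "b"))
  lp <- lump_partners("M one", parts, rec)
  expect_identical(lp$a, "M two")
  expect_identical(lp$b, character(0))
  lp3 <- lump_partners("M three", parts, rec)
  expect_identical(lp3$b, "M two")        # s3 shares g2 with s4, s5
  expect_identical(lp3$a, character(0))   # g2 holds only M three under a
})

test_that("discordance classification covers S/L categories, R flag and H/A context", {
  rec <- cast_records()
  ## study-scope: both methods split m1; merged adds nothing new
  ps <- list(x = pt(s1 = "g1", s2 = "g2", s3 = "g3", s4 = "g4", s5 = "g4",
                    method = "x"),
             y = pt(s1 = "h1", s2 = "h2", s3 = "h3", s4 = "h4", s5 = "h4",
                    method = "y"))
  pa <- list(x = pt(s1 = "g1", s2 = "g2", s3 = "g3", s4 = "g4", s5 = "g4",
                    e1 = "g1", e2 = "g5", method = "x"),
             y = pt(s1 = "h1", s2 = "h2", s3 = "h3", s4 = "h4", s5 = "h4",
                    e1 = "h1", e2 = "h5", method = "y"))
  d <- classify_discordances(rec, ps, pa)
  row1 <- d[d$morphospecies == "M one", ]
  expect_identical(row1$category, "SPLIT")
  expect_false(row1$resolution_flag)            # all methods split: "_"
  expect_identical(row1$context, "H")
  expect_true(all(d$category[d$morphospecies %in% c("M two", "M three")] ==
                    "CONCORDANT"))

  ## only one of two methods splits: R flag
  pa2 <- pa
  pa2$y <- pt(s1 = "h1", s2 = "h1", s3 = "h3", s4 = "h4", s5 = "h4",
              e1 = "h1", e2 = "h5", method = "y")
  ps2 <- ps
  ps2$y <- pt(s1 = "h1", s2 = "h1", s3 = "h3", s4 = "h4", s5 = "h4",
              method = "y")
  d2 <- classify_discordances(rec, ps2, pa2)
  expect_true(d2$resolution_flag[d2$morphospecies == "M one"])

  ## lump appearing only after adding external data: context A, all methods
  ps3 <- list(x = pt(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g3", s5 = "g3",
                     method = "x"),
              y = pt(s1 = "h1", s2 = "h1", s3 = "h2", s4 = "h3", s5 = "h3",
                     method = "y"))
  pa3 <- list(x = pt(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g3", s5 = "g3",
                     e1 = "g1", e2 = "g3", method = "x"),
              y = pt(s1 = "h1", s2 = "h1", s3 = "h2", s4 = "h3", s5 = "h3",
                     e1 = "h1", e2 = "h3", method = "y"))
  d3 <- classify_discordances(rec, ps3, pa3)
  lr <- d3[d3$category == "LUMP", ]
  expect_equal(nrow(lr), 1L)
  expect_identical(lr$context, "A")
  expect_false(lr$resolution_flag)
  expect_match(lr$morphospecies, "M four")
  expect_match(lr$morphospecies, "M three")

  ## method-set mismatch between scopes is an error
  expect_error(classify_discordances(rec, ps3["x"], pa3), "method sets")
})

test_that("every morphospecies lands in exactly one verdict set", {
  for (s in 1:5) {
    sim <- generate_barcodes(synthetic_config(
      n_species = 5, samples_per_species = 4,
      scenarios = list(list(type = "CRYPTIC_SPLIT", species = c(1, 2)),
                       list(type = "LUMP", species = 3)),
      reference_fraction = 0.25, seed = s))
    dm <- p_distance_matrix(sim$sequences)
    study_ids <- sim$records$specimen_id[sim$records$provenance == "STUDY"]
    pa <- list(abgd = abgd_partition(dm, 0.03),
               linkage = single_linkage_partition(dm))
    dms <- subset_pdist(dm, study_ids)
    ps <- list(abgd = abgd_partition(dms, 0.03),
               linkage = single_linkage_partition(dms))
    d <- classify_discordances(sim$records, ps, pa)
    study_labels <- unique(sim$records$morphospecies[
      sim$records$provenance == "STUDY"])
    covered <- unlist(strsplit(d$morphospecies, ", ", fixed = TRUE))
    expect_setequal(intersect(covered, study_labels), study_labels)
    conc <- d$morphospecies[d$category == "CONCORDANT"]
    issue <- setdiff(covered, conc)
    expect_length(intersect(conc, issue), 0L)
    ## unanimity: a "_" flag means every evaluable method is in the set
    for (i in which(!d$resolution_flag & d$category == "SPLIT"))
      expect_setequal(strsplit(d$methods[i], ",")[[1]], c("abgd", "linkage"))
  }
})

test_that("provisional resolution distinguishes separate, grouped and mixed", {
  rec <- make_records(c("p1", "p2", "q1", "e1"),
                      c("Aster sp.", "Aster sp.", "Aster beta", "Aster gamma"),
                      provisional = c(TRUE, TRUE, FALSE, FALSE),
                      provenance = c("STUDY", "STUDY", "STUDY", "EXTERNAL"))
  ## separate under both methods
  pa <- list(a = pt(p1 = "g1", p2 = "g1", q1 = "g2", e1 = "g3", method = "a"),
             b = pt(p1 = "h1", p2 = "h1", q1 = "h2", e1 = "h3", method = "b"))
  r <- resolve_provisional("Aster sp.", pa, rec)
  expect_identical(r$verdict, "SEPARATE")
  expect_identical(r$nearest, "NO_MATCH")

  ## grouped with one described species under all methods
  pa2 <- list(a = pt(p1 = "g1", p2 = "g1", q1 = "g2", e1 = "g1", method = "a"),
              b = pt(p1 = "h1", p2 = "h1", q1 = "h2", e1 = "h1", method = "b"))
  r2 <- resolve_provisional("Aster sp.", pa2, rec)
  expect_identical(r2$verdict, "GROUPED_WITH")
  expect_identical(r2$grouped_with, "Aster gamma")

  ## grouped by one method, separate under the other: mixed
  pa3 <- list(a = pa2$a, b = pa$b)
  r3 <- resolve_provisional("Aster sp.", pa3, rec)
  expect_identical(r3$verdict, "MIXED")
  expect_identical(unname(r3$per_method),
                   c("Aster gamma", "SEPARATE"))

  ## nearest-reference note honors the 5% dissimilarity ceiling
  mt <- data.frame(query_id = "p1", rank = 1L, reference_id = "e1",
                   reference_name = "Aster gamma", p_distance = 0.012,
                   classification = "PROVISIONAL_INVOLVED",
                   stringsAsFactors = FALSE)
  r4 <- resolve_provisional("Aster sp.", pa, rec, matches = mt)
  expect_match(r4$nearest, "Aster gamma")
  mt$p_distance <- 0.09
  r5 <- resolve_provisional("Aster sp.", pa, rec, matches = mt)
  expect_identical(r5$nearest, "NO_MATCH")

  expect_error(resolve_provisional("Aster beta", pa, rec), "not flagged")
})

test_that("summary counts match an independent recount of raw partitions", {
  for (s in 1:4) {
    sim <- generate_barcodes(synthetic_config(
      n_species = 5, samples_per_species = 4,
      scenarios = list(list(type = "PROVISIONAL", fraction = 0.25)),
      reference_fraction = 0.25, seed = 60 + s))
    dm <- p_distance_matrix(sim$sequences)
    parts <- list(abgd = abgd_partition(dm, 0.03),
                  linkage = single_linkage_partition(dm))
    summ <- summarize_concordance(sim$records, parts)
    all_row <- summ$by_class[summ$by_class$taxon_class == "ALL", ]
    study <- sim$records[sim$records$provenance == "STUDY", ]
    expect_equal(all_row$n_specimens, nrow(study))
    expect_equal(all_row$n_morphospecies, length(unique(study$morphospecies)))
    expect_equal(all_row$n_provisional,
                 length(unique(study$morphospecies[study$provisional])))
    ## brute-force group recount: groups holding >= 1 study specimen
    for (m in names(parts)) {
      expected <- length(unique(parts[[m]]$assignment[
        intersect(study$specimen_id, partition_scope(parts[[m]]))]))
      expect_equal(all_row[[m]], expected)
    }
  }
})

test_that("discordance reports serialize with printed R/_ flags", {
  rec <- cast_records()
  ps <- list(x = pt(s1 = "g1", s2 = "g2", s3 = "g3", s4 = "g4", s5 = "g4",
                    method = "x"))
  pa <- list(x = pt(s1 = "g1", s2 = "g2", s3 = "g3", s4 = "g4", s5 = "g4",
                    e1 = "g1", e2 = "g5", method = "x"))
  d <- classify_discordances(rec, ps, pa)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_discordances(d, f)
  back <- utils::read.delim(f)
  expect_identical(back$code[back$morphospecies == "M one"], "S-_-H")
})
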