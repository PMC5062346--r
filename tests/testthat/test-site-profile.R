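test_that("column entropy matches closed forms and the definition", {
  expect_equal(column_entropy(rep("A", 10)), 0)
  expect_equal(column_entropy(c(rep("A", 5), rep("V", 5))), log(2))
  expect_equal(column_entropy(c("L", "L", "S", "E")),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(column_entropy(c("A", "V"), base = 2), 1)
  expect_warning(h <- column_entropy(c("-", "-")), "empty")
  expect_true(is.na(h))
  # gaps excluded by default, counted as a state on request
  expect_equal(column_entropy(c("A", "A", "-")), 0)
  expect_gt(column_entropy(c("A", "A", "-"), gap_policy = "as_state"), 0)
})

test_that("entropy is bounded by the log of the state count", {
  set.seed(3)
  for (rep in 1:50) {
    col <- sample(AA20, sample(2:40, 1), replace = TRUE)
    h <- column_entropy(col)
    k <- length(unique(col))
    expect_gte(h, 0)
    expect_lte(h, log(k) + 1e-12)
    expect_equal(h, oracle_entropy(col), tolerance = 1e-12)
  }
  # equality at log k only for uniform columns
  expect_equal(column_entropy(rep(c("A", "C", "E"), 4)), log(3),
               tolerance = 1e-12)
})

test_that("site classification follows the precedence rules", {
  expect_equal(classify_site(rep("L", 8))$class, "conserved")
  # all four residues share the nonpolar aliphatic group: non-variable
  # despite entropy log(4) > 1.1
  mix <- rep(c("G", "A", "V", "L"), 3)
  cls <- classify_site(mix)
  expect_equal(cls$class, "nonvariable_within_group")
  expect_gt(cls$entropy, 1.1)
  expect_true(is.na(cls$bin))
  # E and Q sit in different groups; H = log 2 lands in the first bin
  eq <- classify_site(c(rep("E", 5), rep("Q", 5)))
  expect_equal(eq$class, "variable")
  expect_equal(eq$bin, "(0.5,0.7]")
  # low-entropy cross-group variation is non-variable
  low <- classify_site(c(rep("E", 49), "S"))
  expect_equal(low$class, "nonvariable")
  expect_error(classify_site(c("A", "B")), "B")
})

test_that("classification agrees with exhaustive case analysis", {
  set.seed(17)
  for (rep in 1:200) {
    col <- sample(AA20, sample(2:4, 1), replace = TRUE)
    n <- sample(3:30, 1)
    col <- sample(col, n, replace = TRUE)
    expect_equal(classify_site(col)$class, oracle_classify(col),
                 info = paste(col, collapse = ""))
  }
})

test_that("variable sites land in the expected entropy bins", {
  # log 2 = 0.693: first bin, right-closed at 0.7
  expect_equal(classify_site(c(rep("E", 2), rep("S", 2)))$bin, "(0.5,0.7]")
  # counts 6/3/1 over three groups: H = 0.898, second bin
  col2 <- c(rep("E", 6), rep("S", 3), "K")
  expect_equal(classify_site(col2)$entropy, 0.8979457, tolerance = 1e-6)
  expect_equal(classify_site(col2)$bin, "(0.7,0.9]")
  # three equal states across groups: log 3 = 1.099, third bin
  expect_equal(classify_site(rep(c("E", "S", "K"), 3))$bin, "(0.9,1.1]")
  # four equal states across groups: log 4 = 1.386, top bin
  expect_equal(classify_site(rep(c("E", "S", "K", "F"), 3))$bin, ">1.1")
})

test_that("consensus conservation uses the modal frequency", {
  col <- c(rep("L", 996), rep("M", 4))
  expect_true(consensus_conserved(col, 0.995))
  col2 <- c(rep("L", 994), rep("M", 6))
  expect_false(consensus_conserved(col2, 0.995))
  expect_warning(expect_false(consensus_conserved(c("-", "-"), 0.995)))
  # threshold 1 reproduces the strict conserved class on gap-free columns
  expect_true(consensus_conserved(rep("A", 7), 1))
  expect_false(consensus_conserved(c(rep("A", 6), "V"), 1))
})

test_that("consensus conservation is monotone in the threshold", {
  set.seed(5)
  for (rep in 1:40) {
    col <- sample(AA20[1:4], 50, replace = TRUE)
    ts <- sort(runif(5, 0.2, 1))
    vals <- purrr::map_lgl(ts, ~ consensus_conserved(col, .x))
    # TRUE at a threshold implies TRUE at every lower threshold
    expect_true(all(diff(as.integer(vals)) <= 0))
  }
})

test_that("deletion events are maximal internal gap runs", {
  aa <- paste(c(rep("L", 9), "-", "-", "-", rep("L", 27), "-",
                rep("L", 10)), collapse = "")
  raln <- fake_raln(c(aa, strrep("L", 50)))
  d <- detect_deletions(raln)
  expect_equal(nrow(d$events), 2L)
  expect_equal(d$events$start, c(10L, 40L))
  expect_equal(d$events$length, c(3L, 1L))
  expect_equal(d$per_sequence$deleted_residues, c(4L, 0L))
})

test_that("terminal gaps are missing data unless counted on request", {
  aa <- paste0("--", strrep("L", 6), "--")
  raln <- fake_raln(c(aa))
  expect_equal(nrow(detect_deletions(raln)$events), 0L)
  counted <- detect_deletions(raln, terminal_policy = "count")
  expect_equal(nrow(counted$events), 2L)
})

test_that("a 13-residue deletion fixture is counted exactly", {
  # emulates the squid-parasite lineage missing 13 residues
  aa <- paste0(strrep("L", 100), strrep("-", 13), strrep("L", 106))
  raln <- fake_raln(c(aa, strrep("L", 219)))
  d <- detect_deletions(raln)
  expect_equal(d$per_sequence$deleted_residues[[1]], 13L)
})

test_that("deletion events reconstruct the gap mask exactly", {
  set.seed(23)
  for (rep in 1:20) {
    L <- 40
    gaps <- sort(sample(5:(L - 4), sample(0:10, 1)))
    chars <- rep("L", L)
    chars[gaps] <- "-"
    raln <- fake_raln(paste(chars, collapse = ""))
    ev <- detect_deletions(raln)$events
    mask <- rep(FALSE, L)
    for (i in seq_len(nrow(ev))) mask[ev$start[i]:ev$end[i]] <- TRUE
    expect_equal(mask, chars == "-")
    if (nrow(ev) > 1) {
      expect_true(all(ev$start[-1] > ev$end[-nrow(ev)] + 1))
    }
  }
})

test_that("the default segment table satisfies the barcode topology", {
  seg <- coi_segments()
  expect_equal(nrow(seg), 11L)
  expect_equal(sum(seg$type == "helix"), 6L)
  expect_equal(sum(seg$type == "loop"), 5L)
  widths <- seg$end - seg$start + 1L
  expect_equal(sum(widths), 219L)
  expect_equal(sum(widths[seg$type == "loop"]), 60L)
  expect_equal(sum(widths[seg$type == "helix"]), 159L)
  # contiguous, ordered, non-overlapping
  expect_equal(seg$start[-1], seg$end[-nrow(seg)] + 1L)
})

test_that("profiling covers every column with a populated row", {
  raln <- fake_raln(c("LLSE", "LLSQ", "LLSE"))
  seg <- tibble::tibble(segment = c("Helix 1", "Loop 1-2"),
                        type = c("helix", "loop"),
                        start = c(1L, 3L), end = c(2L, 4L))
  prof <- profile_alignment(raln, seg)
  expect_s3_class(prof, "site_profile")
  expect_equal(nrow(prof), 4L)
  expect_equal(prof$class, c("conserved", "conserved", "conserved",
                             "variable"))
  expect_equal(prof$segment_type, c("helix", "helix", "loop", "loop"))
  expect_equal(prof$gap_count, rep(0L, 4))
  expect_equal(prof$freqs[[1]][["L"]], 1)
  g <- glance(prof)
  expect_equal(g$n_conserved, 3L)
  expect_equal(g$n_variable, 1L)
})

test_that("segment cross-tabulation reproduces printed count layouts", {
  # fabricate a 219-column profile with 16 conserved helix columns and
  # 7 conserved loop columns over the canonical segment table
  seg <- coi_segments()
  st <- segment_of(1:219, seg)
  helix_pos <- which(st$segment_type == "helix")
  loop_pos <- which(st$segment_type == "loop")
  class <- rep("nonvariable", 219)
  class[helix_pos[1:16]] <- "conserved"
  class[loop_pos[1:7]] <- "conserved"
  prof <- tibble::tibble(position = 1:219, class = class,
                         entropy = 0.1,
                         segment = st$segment,
                         segment_type = st$segment_type)
  tab <- class_by_segment_table(prof, "conserved")
  expect_equal(unclass(tab),
               matrix(c(16L, 143L, 7L, 53L), 2, 2, byrow = TRUE,
                      dimnames = list(c("helix", "loop"), c("yes", "no"))))
  expect_equal(sum(tab), 219L)
  none <- class_by_segment_table(prof, "no_such_class")
  expect_equal(as.vector(none), c(0L, 0L, 159L, 60L))
  expect_equal(rowSums(tab), c(helix = 159L, loop = 60L))
})

test_that("function predicates select sites by entropy", {
  prof <- tibble::tibble(position = 1:4,
                         class = c("variable", "variable", "conserved",
                                   "nonvariable"),
                         entropy = c(1.5, 0.6, 0, 0.2),
                         segment = c("H", "H", "L", "L"),
                         segment_type = c("helix", "helix", "loop", "loop"))
  tab <- class_by_segment_table(prof, function(p) p$entropy > 1.1)
  expect_equal(as.vector(tab), c(1L, 0L, 1L, 2L))
  expect_error(class_by_segment_table(
    dplyr::mutate(prof, segment_type = NA_character_), "conserved"),
    "segment")
})
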