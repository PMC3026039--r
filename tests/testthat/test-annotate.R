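test_that("family rule 1 accepts a contiguous internal stretch at >= 90%", {
  fam <- small_library()[[1]]
  cons <- family_consensus(fam)
  seg <- family_segments(fam)
  th <- annotation_thresholds()

  # 420 bp of internal region at ~92% identity -> rule 1
  a <- fake_alignment(cons, seg$start[2] + 100, seg$start[2] + 519,
                      n_mismatch = 33)
  cand <- fake_candidate(fam, list(a))
  res <- assign_family(cand, fam, th)
  expect_true(res$accepted)
  expect_equal(res$rule, 1L)

  # 399 bp internal at 95% + 80 of a >= 200 bp LTR at 95% -> both rules fail
  b1 <- fake_alignment(cons, seg$start[2] + 100, seg$start[2] + 498,
                       n_mismatch = 20)
  b2 <- fake_alignment(cons, seg$start[1], seg$start[1] + 79, n_mismatch = 4,
                       gstart = 5000)
  cand2 <- fake_candidate(fam, list(b1, b2))
  expect_false(assign_family(cand2, fam, th)$accepted)
})

test_that("family rule 2 accepts >= 90% identity over half the LTR", {
  fam <- small_library()[[1]]
  cons <- family_consensus(fam)
  seg <- family_segments(fam)
  ltr_len <- nchar(fam$ltr5)
  half <- ceiling(ltr_len / 2)

  # half the LTR at ~91% identity, nothing else -> rule 2
  a <- fake_alignment(cons, seg$start[1], seg$start[1] + half - 1,
                      n_mismatch = floor(0.09 * half))
  cand <- fake_candidate(fam, list(a))
  res <- assign_family(cand, fam, annotation_thresholds())
  expect_true(res$accepted)
  expect_equal(res$rule, 2L)

  # same coverage at 85% identity -> rejected
  b <- fake_alignment(cons, seg$start[1], seg$start[1] + half - 1,
                      n_mismatch = ceiling(0.15 * half))
  expect_false(assign_family(fake_candidate(fam, list(b)), fam,
                             annotation_thresholds())$accepted)

  expect_error(assign_family(cand, list(name = "x"), annotation_thresholds()),
               "segmentation")
})

test_that("condition classification follows the alignment evidence", {
  fam <- small_library()[[1]]
  cons <- family_consensus(fam)
  seg <- family_segments(fam)
  th <- annotation_thresholds()
  bg <- background()

  # LTR-only evidence with clean flanks -> solo-LTR
  a <- fake_alignment(cons, seg$start[1], seg$end[1], gstart = 30000)
  expect_identical(classify_condition(fake_candidate(fam, list(a)), fam, bg, th),
                   "solo-LTR")

  # LTR5 + 2 kb of internal region -> proviral
  b <- fake_alignment(cons, seg$start[1], seg$start[2] + 2000, gstart = 30000)
  expect_identical(classify_condition(fake_candidate(fam, list(b)), fam, bg, th),
                   "proviral")

  # LTR-only with a long N track where the internal region would lie -> unknown
  g_n <- paste0(substr(bg, 1, 30000 + nchar(fam$ltr5) - 1),
                paste(rep("N", 4000), collapse = ""),
                substr(bg, 30000 + nchar(fam$ltr5) + 4000, nchar(bg)))
  expect_identical(classify_condition(fake_candidate(fam, list(a)), fam, g_n, th),
                   "unknown")
})

test_that("structural variation is called from gap runs at the 10 bp floor", {
  fam <- small_library()[[1]]
  cons <- family_consensus(fam)
  th <- annotation_thresholds()
  seg <- family_segments(fam)
  s0 <- seg$start[2] + 50  # inside the internal region

  # construct an alignment with copy-row gap runs of 9, 10 and 250 bp
  span <- substr(cons, s0, s0 + 999)
  ch <- strsplit(span, "")[[1]]
  copy <- ch
  copy[101:109] <- "-"   # 9 bp: below threshold
  copy[301:310] <- "-"   # 10 bp
  copy[501:750] <- "-"   # 250 bp
  al <- list(copy_aln = paste(copy, collapse = ""),
             cons_aln = span, cons_start = s0, cons_end = s0 + 999,
             reliable = TRUE)
  sv <- call_sv(al, fam, th)
  expect_equal(sv$type, c("del", "del"))
  expect_equal(sv$size, c(10, 250))
  expect_equal(sv$offset, c(s0 + 300, s0 + 500))
  expect_true(all(sv$ltr_flag == "none"))
})

test_that("insertions matching nearby consensus are re-typed as duplications", {
  fam <- small_library()[[1]]
  cons <- family_consensus(fam)
  th <- annotation_thresholds()
  seg <- family_segments(fam)
  s0 <- seg$start[2] + 10

  span <- substr(cons, s0, s0 + 599)
  dup_seq <- substr(cons, s0 + 200, s0 + 259)        # 60 bp duplication
  alien <- ltrscape:::random_sequence(60, 0.5)        # unrelated insertion
  mk <- function(ins) {
    ca <- paste0(substr(span, 1, 300), ins, substr(span, 301, 600))
    cb <- paste0(substr(span, 1, 300), paste(rep("-", 60), collapse = ""),
                 substr(span, 301, 600))
    list(copy_aln = ca, cons_aln = cb, cons_start = s0, cons_end = s0 + 599,
         reliable = TRUE)
  }
  sv_dup <- call_sv(mk(dup_seq), fam, th)
  expect_equal(sv_dup$type, "dup")
  sv_ins <- call_sv(mk(alien), fam, th)
  expect_equal(sv_ins$type, "ins")
  expect_equal(sv_ins$size, 60)
})

test_that("events in the LTR segments carry the LTR flag", {
  fam <- small_library()[[1]]
  cons <- family_consensus(fam)
  seg <- family_segments(fam)
  span <- substr(cons, 1, seg$end[1])   # the 5' LTR
  ch <- strsplit(span, "")[[1]]
  ch[50:69] <- "-"
  al <- list(copy_aln = paste(ch, collapse = ""), cons_aln = span,
             cons_start = 1, cons_end = seg$end[1], reliable = TRUE)
  sv <- call_sv(al, fam, annotation_thresholds())
  expect_equal(sv$ltr_flag, "LTR5")
  expect_identical(sv_string(sv), "del20(5′)")
})

test_that("the partial rule uses a strict 3% deletion threshold", {
  fam <- small_library()[[1]]
  cons <- family_consensus(fam)
  L <- nchar(cons)
  th <- annotation_thresholds()
  mk <- function(del_total) {
    span <- substr(cons, 1, L)
    ch <- strsplit(span, "")[[1]]
    if (del_total > 0) ch[1001:(1000 + del_total)] <- "-"
    list(copy_aln = paste(ch, collapse = ""), cons_aln = span,
         cons_start = 1, cons_end = L, reliable = TRUE)
  }
  just_over <- ceiling(0.03 * L) + 1
  exactly <- floor(0.03 * L)
  expect_true(flag_partial(mk(just_over), fam, "proviral", c(TRUE, TRUE), th))
  if (exactly == 0.03 * L)  # exact 3%: "exceeds" is strict
    expect_false(flag_partial(mk(exactly), fam, "proviral", c(TRUE, TRUE), th))
  expect_true(flag_partial(mk(0), fam, "solo-LTR", c(TRUE, TRUE), th))
})

test_that("pairwise-deletion divergence excludes gap and N columns", {
  expect_equal(compute_divergence(strrep("A", 300), strrep("A", 300)), 0)

  # 100 columns: 5 mismatches, 8 gap columns, 2 N columns -> 5/90
  a <- c(rep("A", 85), rep("C", 5), rep("-", 8), rep("N", 2))
  b <- rep("A", 100)
  expect_equal(compute_divergence(paste(a, collapse = ""),
                                  paste(b, collapse = "")), 5 / 90)

  # under 50 comparable columns -> undetermined
  expect_true(is.na(compute_divergence(strrep("A", 49), strrep("A", 49))))
})

test_that("divergence agrees with an independent per-column recount", {
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  for (i in 1:100) {
    n <- sample(60:200, 1)
    a <- sample(c(bases, "-", "N"), n, replace = TRUE,
                prob = c(rep(0.23, 4), 0.05, 0.03))
    b <- sample(c(bases, "-", "N"), n, replace = TRUE,
                prob = c(rep(0.23, 4), 0.05, 0.03))
    est <- compute_divergence(paste(a, collapse = ""), paste(b, collapse = ""),
                              min_cols = 1)
    comp <- a %in% bases & b %in% bases
    expect_equal(est, sum(a[comp] != b[comp]) / sum(comp))
  }
})

test_that("TSD detection returns the longest duplicated junction word", {
  expect_identical(detect_tsd("GGGGGCTTAT", "CTTATGGGGG"), "CTTAT")
  expect_identical(detect_tsd("GGGGGGCTTC", "CTTCGGGGGG"), "CTTC")
  expect_null(detect_tsd("GGGGGGGGGG", "TTTTTTTTTT"))
  expect_true(is.na(detect_tsd("GGG", "CTTATGGGGG")))
  # prefers 6 over shorter duplications when both match
  expect_identical(detect_tsd("GGGGTACGTA", "TACGTAGGGG"), "TACGTA")
})

test_that("SV strings round-trip through the table dialect", {
  sv <- data.frame(type = c("del", "ins", "dup"),
                   size = c(120L, 45L, 30L),
                   ltr_flag = c("LTR5", "none", "LTR3"),
                   stringsAsFactors = FALSE)
  s <- sv_string(sv)
  expect_identical(s, "del120(5′), ins45, dup30(3′)")
  back <- parse_sv_string(s)
  expect_equal(back, sv)
  # ASCII prime and dash-separated same-position events also parse
  two <- parse_sv_string("del120(5'), ins45-dup30")
  expect_equal(two$type, c("del", "ins", "dup"))
  expect_identical(sv_string(NULL), "ND")
  expect_identical(sv_string(sv[0, ]), "No")
  expect_null(parse_sv_string("ND"))
  expect_warning(bad <- parse_sv_string("del120, blob9"), "malformed")
  expect_null(bad)
})

test_that("mosaic copies are flagged as unreliable alignments", {
  lib <- small_library()
  famA <- lib[[1]]; famB <- lib[[2]]
  consA <- family_consensus(famA)
  half <- floor(nchar(consA) / 2)
  mosaic <- paste0(substr(consA, 1, half),
                   substr(family_consensus(famB), 1, nchar(consA) - half))
  pl <- plant(mosaic, site = 25000)
  # the whole locus taken as one candidate against family A's full consensus
  a1 <- fake_alignment(consA, 1, half, gstart = pl$start)
  a2 <- fake_alignment(consA, nchar(consA) - 30, nchar(consA),
                       gstart = pl$end - 30)
  cand <- fake_candidate(famA, list(a1, a2))
  al <- align_to_consensus(cand, famA, pl$genome[[1]])
  expect_false(al$reliable)

  # a clean copy of the same length is reliable
  clean <- plant(consA, site = 25000)
  b1 <- fake_alignment(consA, 1, nchar(consA), gstart = clean$start)
  al2 <- align_to_consensus(fake_candidate(famA, list(b1)), famA,
                            clean$genome[[1]])
  expect_true(al2$reliable)
  expect_equal(al2$aligned_identity, 1)
})

test_that("annotation partitions candidates and reconciles counts", {
  run <- shared_sim_run()
  copies <- run$copies
  cnt <- attr(copies, "counts")
  expect_equal(unname(cnt["candidates"]),
               unname(cnt["rejected_family"] + cnt["overlap_dropped"] +
                      cnt["annotated"]))
  expect_equal(sum(copies$condition %in% c("proviral", "solo-LTR", "unknown")),
               nrow(copies))
  expect_true(all(copies$end >= copies$start))
  expect_true(all(copies$partial[copies$condition == "solo-LTR"]))
  expect_true(all(is.na(copies$divergence) |
                  (copies$divergence >= 0 & copies$divergence <= 1)))
  # complete copies carry no SV events
  comp <- copies[!is.na(copies$fragmentation) &
                 copies$fragmentation == "complete", ]
  expect_true(all(comp$sv == "No"))
})
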