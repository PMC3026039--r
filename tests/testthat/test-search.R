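test_that("k-mer index lookup is exact and skips N", {
  idx <- index_genome(c(chr = "ACGTACGTACGT"), k = 8)
  expect_equal(index_lookup(idx, "ACGTACGT"), c(1, 5))
  expect_equal(index_lookup(idx, "CGTACGTA"), 2)
  expect_length(index_lookup(idx, "ACGTACGN"), 0)

  idx2 <- index_genome(c(chr = "ACGTNCGTACGTACGTA"), k = 8)
  # k-mers overlapping the N are not indexed
  expect_length(index_lookup(idx2, "ACGTNCGT"), 0)
  expect_equal(index_lookup(idx2, "CGTACGTA"), c(6, 10))
})

test_that("every indexed k-mer occurs at its recorded positions", {
  g <- ltrscape:::random_sequence(10000, 0.5)
  k <- 11
  idx <- index_genome(c(chr = g), k)
  # brute-force re-scan for a sample of query k-mers drawn from the genome
  set.seed(1)
  for (p in sample(1:(10000 - k), 60)) {
    km <- substr(g, p, p + k - 1)
    hits <- index_lookup(idx, km)
    brute <- c()
    for (q in 1:(nchar(g) - k + 1))
      if (substr(g, q, q + k - 1) == km) brute <- c(brute, q)
    expect_equal(sort(hits), brute)
  }
})

test_that("seed extension recovers planted segments at the right identity", {
  fam <- small_library()[[1]]
  cons <- family_consensus(fam)
  # verbatim copy -> identity 1 over the full span
  pl <- plant(cons, site = 20000)
  seedpos <- 2500  # within the copy
  r <- extend_seed(pl$genome[[1]], cons, pl$start + seedpos - 1, seedpos)
  expect_equal(r$identity, 1.0)
  expect_lte(r$gstart, pl$start + 5)
  expect_gte(r$gend, pl$end - 5)

  # 5% diverged copy >= 1 kb -> identity within 0.95 +/- 0.01
  m <- mutate_copy(cons, 0.05, list(), seed = 21)
  pl2 <- plant(m$seq, site = 20000)
  # find an exact 11-mer seed shared by copy and consensus
  q <- which(strsplit(m$seq, "")[[1]] == strsplit(cons, "")[[1]])
  run <- rle(diff(q) == 1)
  seedq <- q[1]
  for (i in seq_along(q)) {
    if (i + 10 <= length(q) && all(q[i:(i + 10)] == q[i] + 0:10)) {
      seedq <- q[i]; break
    }
  }
  r2 <- extend_seed(pl2$genome[[1]], cons, pl2$start + seedq - 1, seedq)
  expect_gte(r2$gend - r2$gstart + 1, 1000)
  expect_lt(abs(r2$identity - 0.95), 0.01)
})

test_that("extension scores equal the exhaustive local-alignment oracle", {
  # fixture pairs <= 200 bp sharing an exact 11-mer seed
  set.seed(42)
  for (i in 1:25) {
    core <- ltrscape:::random_sequence(sample(40:120, 1), 0.5)
    a <- paste0(ltrscape:::random_sequence(sample(10:40, 1), 0.5), core,
                ltrscape:::random_sequence(sample(10:40, 1), 0.5))
    # b carries a mutated core so the best alignment is the core match
    mcore <- mutate_copy(core, runif(1, 0, 0.06), list(), seed = i)$seq
    b <- paste0(ltrscape:::random_sequence(sample(10:40, 1), 0.5), mcore,
                ltrscape:::random_sequence(sample(10:40, 1), 0.5))
    # locate a shared exact 11-mer to seed from
    seed_at <- NA
    ca <- strsplit(core, "")[[1]]; cb <- strsplit(mcore, "")[[1]]
    eq <- ca == cb
    for (p in seq_len(length(eq) - 10)) {
      if (all(eq[p:(p + 10)])) { seed_at <- p; break }
    }
    if (is.na(seed_at)) next
    gpos <- regexpr(core, a, fixed = TRUE)[1] + seed_at - 1
    qpos <- regexpr(mcore, b, fixed = TRUE)[1] + seed_at - 1
    r <- extend_seed(a, b, gpos, qpos)
    expect_equal(r$score, sw_oracle_score(a, b), info = paste("pair", i))
  }
})

test_that("scanning recovers planted copies with both strand conventions", {
  lib <- small_library()
  fam <- lib[[1]]
  m <- mutate_copy(family_consensus(fam), 0.03, list(), seed = 31)
  plus <- plant(m$seq, site = 25000)
  minus <- plant(rev_comp(m$seq), site = 25000)

  c1 <- scan_genome(lib, plus$genome)
  expect_length(c1, 1)
  expect_identical(c1[[1]]$strand, "+")
  expect_lte(abs(c1[[1]]$gstart - plus$start), 5)
  expect_lte(abs(c1[[1]]$gend - plus$end), 5)

  c2 <- scan_genome(lib, minus$genome)
  expect_length(c2, 1)
  expect_identical(c2[[1]]$strand, "-")
  expect_lte(abs(c2[[1]]$gstart - minus$start), 5)
  expect_lte(abs(c2[[1]]$gend - minus$end), 5)
})

test_that("scanning a reverse-complemented genome mirrors the copy set", {
  lib <- small_library()[1]
  fam <- lib[[1]]
  m <- mutate_copy(family_consensus(fam), 0.02, list(), seed = 32)
  pl <- plant(m$seq, site = 18000, bg = background(40000))
  g <- pl$genome
  grc <- c(chr = rev_comp(g[[1]]))
  n <- nchar(g[[1]])

  cf <- scan_genome(lib, g)
  cr <- scan_genome(lib, grc)
  expect_equal(length(cf), length(cr))
  expect_length(cf, 1)
  expect_identical(cr[[1]]$strand, setdiff(c("+", "-"), cf[[1]]$strand))
  expect_equal(cr[[1]]$gstart, n - cf[[1]]$gend + 1)
  expect_equal(cr[[1]]$gend, n - cf[[1]]$gstart + 1)
})

test_that("pure random genomes yield no long high-identity candidates", {
  lib <- build_family_library(3, seed = 33)
  for (s in 1:2) {
    g <- c(chr = with(list(), {
      set.seed(1000 + s); ltrscape:::random_sequence(400000, 0.45)
    }))
    cands <- scan_genome(lib, g)
    confident <- Filter(function(cd) {
      len <- cd$gend - cd$gstart + 1
      ident <- sum(vapply(cd$alignments, function(a) a$identity * a$ncol,
                          numeric(1))) /
               sum(vapply(cd$alignments, `[[`, numeric(1), "ncol"))
      len >= 400 && ident >= 0.90
    }, cands)
    expect_length(confident, 0)
  }
})

test_that("chaining bridges large internal deletions without fusing tandems", {
  lib <- small_library()
  fam <- lib[[1]]
  cons <- family_consensus(fam)
  # one copy with a 2.8-kb internal deletion -> a single chained candidate
  m <- mutate_copy(cons, 0.01,
                   list(list(type = "del", size = 2800, offset = 1200)),
                   seed = 34)
  pl <- plant(m$seq, site = 25000)
  cd <- scan_genome(lib, pl$genome)
  expect_length(cd, 1)
  expect_gte(length(cd[[1]]$alignments), 2)
  expect_lte(abs(cd[[1]]$gstart - pl$start), 5)
  expect_lte(abs(cd[[1]]$gend - pl$end), 5)

  # two tandem copies 100 bp apart -> two candidates, not one
  m1 <- mutate_copy(cons, 0.01, list(), seed = 35)$seq
  m2 <- mutate_copy(cons, 0.01, list(), seed = 36)$seq
  bg <- background()
  g <- c(chr = paste0(substr(bg, 1, 20000), m1,
                      substr(bg, 20001, 20100), m2,
                      substr(bg, 20101, nchar(bg))))
  cds <- scan_genome(lib, g)
  expect_length(cds, 2)
})

test_that("an empty or missing library is rejected; empty genome is empty", {
  expect_error(scan_genome(structure(list(), class = "ltr_library"),
                           c(chr = "ACGT")), "non-empty")
  out <- scan_genome(small_library(), c(chr = ""))
  expect_length(out, 0)
})
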