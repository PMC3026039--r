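test_that("PE derivation walks 3 Mb of euchromatin from the PH boundary", {
  # an X-like arm: euchromatin distal, PH proximal at the right end
  map <- compartment_map(data.frame(
    arm = "X",
    start = c(1, 19928575),
    end = c(19928574, 24393108),
    label = c("EU", "PH")))
  out <- derive_pericentromeric_euchromatin(map)
  pe <- out[out$label == "PE", ]
  expect_equal(nrow(pe), 1)
  expect_equal(pe$end, 19928574)
  expect_equal(pe$end - pe$start + 1, 3000000)
  npe <- out[out$label == "NPE", ]
  expect_equal(npe$end, pe$start - 1)

  # an explicit coordinate list overrides the derivation (the published X
  # PE: 16,928,574-19,928,574)
  out2 <- derive_pericentromeric_euchromatin(
    map, pe_override = list(X = data.frame(start = 16928574, end = 19928574)))
  pe2 <- out2[out2$label == "PE", ]
  expect_equal(pe2$start, 16928574)
  expect_equal(pe2$end, 19928574)
})

test_that("PE derivation skips intercalary heterochromatin islands", {
  # 2L-like: PH proximal at the left, a DIH island inside the walk
  map <- compartment_map(data.frame(
    arm = "2L",
    start = c(1, 2000001, 4000001, 4500001),
    end = c(2000000, 4000000, 4500000, 10000000),
    label = c("PH", "EU", "DIH", "EU")))
  out <- derive_pericentromeric_euchromatin(map)
  pe <- out[out$label == "PE", ]
  # two PE pieces around the DIH island summing to exactly 3 Mb
  expect_equal(nrow(pe), 2)
  expect_equal(sum(pe$end - pe$start + 1), 3000000)
  expect_equal(pe$start[1], 2000001)
  expect_true(all(out$label[out$start == 4000001] == "DIH"))

  # published 2L PE segments (split by an intercalary island) sum to ~3 Mb
  seg <- c(5042389 - 2487770 + 1, 6460609 - 6015228 + 1)
  expect_equal(sum(seg), 3000002)
})

test_that("arms without a PH anchor or short of euchromatin warn", {
  map <- compartment_map(data.frame(arm = "U", start = 1, end = 1e6,
                                    label = "EU"))
  expect_warning(out <- derive_pericentromeric_euchromatin(map), "PH")
  expect_true(all(out$label == "NPE"))

  map2 <- compartment_map(data.frame(arm = "S", start = c(1, 2000001),
                                     end = c(2000000, 4000000),
                                     label = c("PH", "EU")))
  expect_warning(out2 <- derive_pericentromeric_euchromatin(map2), "short")
  expect_equal(sum(out2$label == "PE"), 1)
  expect_equal(sum(out2$end[out2$label == "PE"] -
                   out2$start[out2$label == "PE"] + 1), 2000000)
})

test_that("compartment assignment uses the midpoint rule", {
  map <- compartment_map(data.frame(
    arm = "2L", start = c(1, 1001, 2001), end = c(1000, 2000, 3000),
    label = c("PH", "EU", "DIH")))
  copies <- data.frame(arm = "2L",
                       start = c(500, 950, 980, 2500, 100),
                       end = c(600, 1050, 1200, 2600, 200))
  out <- assign_compartment(copies, map)
  # copy 2 midpoint 1000 -> PH; copy 3 midpoint 1090 -> EU (straddles, takes
  # the midpoint's side)
  expect_equal(out$compartment, c("PH", "PH", "EU", "DIH", "PH"))

  unmapped <- assign_compartment(data.frame(arm = "zz", start = 1, end = 2), map)
  expect_true(is.na(unmapped$compartment))
})

test_that("compartment assignment matches a brute-force label lookup", {
  set.seed(11)
  map <- compartment_map(data.frame(
    arm = "A", start = c(1, 30001, 60001), end = c(30000, 60000, 100000),
    label = c("PH", "EU", "CIH")))
  copies <- data.frame(arm = "A",
                       start = sample(1:99000, 200))
  copies$end <- copies$start + sample(100:900, 200, replace = TRUE)
  copies$end <- pmin(copies$end, 100000)
  out <- assign_compartment(copies, map)
  for (i in seq_len(nrow(copies))) {
    mid <- floor((copies$start[i] + copies$end[i]) / 2)
    lab <- map$label[map$start <= mid & map$end >= mid]
    expect_identical(out$compartment[i], lab)
  }
})

test_that("single-linkage clustering honors the 10-kb edge rule", {
  # A-B 8 kb, B-C 8 kb, A-C 16.5 kb -> one cluster by transitivity
  copies <- data.frame(id = c("A", "B", "C"), arm = "2L",
                       start = c(1000, 9500, 18000),
                       end = c(1500, 10000, 18500))
  out <- cluster_insertions(copies, 10000)
  expect_equal(length(unique(out$cluster)), 1)
  expect_equal(attr(out, "n_in_clusters"), 3)

  # exactly 10,000 bp apart -> linked; 10,001 -> not
  at <- data.frame(id = 1:2, arm = "x", start = c(1000, 12001),
                   end = c(2000, 12500))
  expect_equal(attr(cluster_insertions(at, 10000), "n_in_clusters"), 2)
  at2 <- data.frame(id = 1:2, arm = "x", start = c(1000, 12002),
                    end = c(2000, 12500))
  expect_equal(attr(cluster_insertions(at2, 10000), "n_in_clusters"), 0)

  # the start-to-start switch measures a different distance
  st <- data.frame(id = 1:2, arm = "x", start = c(1000, 11500),
                   end = c(9000, 12000))
  expect_equal(attr(cluster_insertions(st, 10000, method = "edge"),
                    "n_in_clusters"), 2)
  expect_equal(attr(cluster_insertions(st, 10000, method = "start"),
                    "n_in_clusters"), 0)
})

test_that("clustering matches the brute-force connected components", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(5:40, 1)
    start <- sort(sample(1:500000, n))
    end <- start + sample(100:8000, n, replace = TRUE)
    copies <- data.frame(id = seq_len(n), arm = "A", start = start, end = end)
    out <- cluster_insertions(copies, 10000)
    oracle <- brute_force_clusters(start, end, 10000)
    # identical partitions
    expect_equal(length(unique(out$cluster)), length(unique(oracle)))
    same_impl <- outer(out$cluster, out$cluster, "==")
    same_orac <- outer(oracle, oracle, "==")
    expect_true(all(same_impl == same_orac))
  }
})

test_that("gene associations follow the 1-kb flank and exon rules", {
  genes <- data.frame(arm = "2L", gene_id = c("MYD", "G2"),
                      start = c(10000, 40000), end = c(15000, 44000),
                      strand = c("+", "-"))
  exons <- data.frame(gene_id = c("MYD", "MYD", "G2"),
                      start = c(10000, 14000, 40000),
                      end = c(11000, 15000, 44000))
  # copy 159 bp upstream of MYD (+ strand: upstream = left)
  up <- data.frame(id = "c1", arm = "2L", start = 9000, end = 9841)
  a1 <- associate_genes(up, genes, exons)
  expect_equal(a1$proximity, 159)
  expect_identical(a1$region, "5′")

  # copy inside MYD between the exons -> intron, proximity 0
  intron <- data.frame(id = "c2", arm = "2L", start = 12000, end = 12500)
  a2 <- associate_genes(intron, genes, exons)
  expect_equal(a2$proximity, 0)
  expect_identical(a2$region, "intron")

  # copy overlapping an exon -> exon
  ex <- data.frame(id = "c3", arm = "2L", start = 10500, end = 11500)
  expect_identical(associate_genes(ex, genes, exons)$region, "exon")

  # 1001 bp away -> no association; 1000 -> associated
  far <- data.frame(id = "c4", arm = "2L", start = 16001, end = 16500)
  expect_equal(nrow(associate_genes(far, genes, exons)), 0)
  edge <- data.frame(id = "c5", arm = "2L", start = 16000, end = 16500)
  a5 <- associate_genes(edge, genes, exons)
  expect_equal(a5$proximity, 1000)
  # + strand, right side -> 3'
  expect_identical(a5$region, "3′")

  # minus-strand gene: left side is 3'
  left_of_g2 <- data.frame(id = "c6", arm = "2L", start = 39500, end = 39800)
  expect_identical(associate_genes(left_of_g2, genes, exons)$region, "3′")

  # a copy may associate with several genes
  both <- data.frame(id = "c7", arm = "2L", start = 15500, end = 39500)
  expect_equal(nrow(associate_genes(both, genes, exons)), 2)
})

test_that("region statistics count midpoints and truncate base pairs", {
  copies <- data.frame(arm = "A", start = c(100, 900, 5000),
                       end = c(300, 1200, 5400),
                       condition = c("proviral", "solo-LTR", "proviral"),
                       divergence = c(0.01, 0.02, NA),
                       fragmentation = c("complete", NA, "moderately-fragmented"),
                       cluster_size = c(1, 1, 1))
  regions <- data.frame(arm = "A", start = 1, end = 1000, label = "R1")
  out <- region_density(copies, regions)
  expect_equal(out$n_insertions, 1)         # midpoints 200, 1050, 5200
  expect_equal(out$ltr_bp, 201 + 101)       # truncation at the border
  expect_equal(out$per_mb, 1 / 0.001)
  expect_equal(out$mean_divergence, 1)      # percent

  empty <- region_density(copies, data.frame(arm = "A", start = 2000,
                                             end = 3000, label = "E"))
  expect_equal(empty$n_insertions, 0)
  expect_equal(empty$ltr_bp, 0)
  expect_error(region_density(copies, data.frame(arm = "A", start = 10,
                                                 end = 5, label = "bad")),
               "region")
})

test_that("windowed densities conserve counts and split straddlers", {
  # one 5-kb copy fully inside a 50-kb window -> 10% density
  copies <- data.frame(start = 10001, end = 15000)
  w <- windowed_density(copies, arm_length = 100000, window = 50000)
  expect_equal(w$density_pct, c(10, 0))

  # straddling copy splits proportionally
  copies2 <- data.frame(start = 48001, end = 52000)
  w2 <- windowed_density(copies2, arm_length = 100000, window = 50000)
  expect_equal(w2$te_bp, c(2000, 2000))

  # sum of window counts equals the arm's copy count
  set.seed(31)
  many <- data.frame(start = sample(1:99000, 120))
  many$end <- pmin(many$start + 500, 100000)
  w3 <- windowed_density(many, arm_length = 100000, window = 7000)
  expect_equal(sum(w3$count), 120)
  # last short window is normalized by its true length
  expect_equal(w3$end[nrow(w3)], 100000)
})

test_that("breakpoint neighborhoods report densities by coordinate rule", {
  arm_len <- 1000000
  bp <- c(300000, 700000)
  # copies planted only inside the two 50-kb flanks of the proximal breakpoint
  te <- data.frame(start = c(260000, 305000), end = c(262000, 307000))
  out <- suppressWarnings(breakpoint_neighborhood_density(te, arm_len, bp))
  get <- function(r) out$density_pct[out$region == r]
  expect_gt(get("prox_bp_left"), 3)
  expect_gt(get("prox_bp_right"), 3)
  expect_lt(get("inside"), 0.6)
  expect_equal(get("dist_bp_left"), 0)

  # proximal + inside + distal tile the analyzed bounds exactly
  widths <- out$end - out$start + 1
  expect_equal(sum(widths[out$region %in% c("proximal", "inside", "distal")]),
               arm_len)

  # uniform placement -> all regions near the global density
  set.seed(41)
  starts <- sample(1:990000, 600)
  te2 <- data.frame(start = starts, end = starts + 999)
  out2 <- suppressWarnings(breakpoint_neighborhood_density(te2, arm_len, bp))
  global <- sum(te2$end - te2$start + 1) / arm_len * 100
  big <- out2[out2$region %in% c("proximal", "inside", "distal",
                                 "centered_prox"), ]
  expect_true(all(abs(big$density_pct - global) < 10))

  w <- capture_warnings(
    breakpoint_neighborhood_density(te, arm_len, c(20000, 700000)))
  expect_true(any(grepl("truncated", w)))
})
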