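# Small noiseless CDKO screens with fixed per-gene fitness: closed-form
# expectations hold exactly along the whole scoring chain.
noiselessSim <- function(lib, dd, gamma = numeric(0), f = NULL, seed = 1) {
  truth <- screenTruth(depth = 1000, tau = 0, sigma_construct = 0,
                       count_noise = FALSE, gamma = gamma)
  if (!is.null(f)) truth$f_gene <- f
  simulateCdkoScreen(dd, lib, truth, 2, seed = seed)
}

test_that("construct LFCs are zero when Tend equals T0 and symmetric in replicates", {
  lib <- makeLibrary(3, 2, 1)
  dd <- buildDualDesign(lib)
  ids <- constructIds(dd)
  des <- simpleDesign(2, 2)
  base <- seq(20, 20 + 5 * (length(ids) - 1), by = 5)
  m <- cbind(T0_1 = base, T0_2 = base, Tend_1 = base, Tend_2 = base)
  rownames(m) <- ids
  lfc <- constructLfc(ScreenCountSet(m, des), dd)
  expect_equal(max(abs(lfc)), 0)

  # permuting the replicate columns leaves the average unchanged
  m2 <- m
  m2[, "Tend_1"] <- 3 * base
  des_perm <- des[c(2, 1, 4, 3), ]
  lfc_a <- constructLfc(ScreenCountSet(m2, des), dd)
  lfc_b <- constructLfc(ScreenCountSet(m2[, des_perm$sample_id], des_perm), dd)
  expect_equal(lfc_b, lfc_a)
})

test_that("missing constructs are treated as zero counts, with a message", {
  lib <- makeLibrary(2, 1, 1)
  dd <- buildDualDesign(lib)
  ids <- constructIds(dd)
  des <- simpleDesign()
  m <- matrix(100, length(ids) - 2, 2,
              dimnames = list(ids[-(1:2)], des$sample_id))
  expect_message(lfc <- constructLfc(ScreenCountSet(m, des), dd),
                 "2 design construct")
  expect_equal(length(lfc), length(ids))
  expect_equal(unname(lfc[ids[1]]), 0)  # log2(1/1) with pseudocount
})

test_that("single-gene fitness recovers planted values exactly and scales linearly", {
  lib <- makeLibrary(5, 3, 2)
  dd <- buildDualDesign(lib)
  f <- setNames(c(-1.5, -0.5, 0, 0.75, 2), targetGenes(lib))
  sim <- noiselessSim(lib, dd, f = f)
  lfc <- constructLfc(sim$counts, dd, pseudocount = 0)
  fit <- singleGeneFitness(lfc, dd, lib)
  expect_equal(fit$f_gene[names(f)], f, tolerance = 1e-12)
  expect_equal(fit$f_guide, sim$truth$f_guide[names(fit$f_guide)],
               tolerance = 1e-12)
  # safe guides sit at background
  expect_equal(max(abs(fit$f_guide[safeGuides(lib)])), 0)

  sim2 <- noiselessSim(lib, dd, f = 2 * f)
  fit2 <- singleGeneFitness(constructLfc(sim2$counts, dd, pseudocount = 0),
                            dd, lib)
  expect_equal(fit2$f_gene[names(f)], 2 * f, tolerance = 1e-12)
})

test_that("all SL scores vanish on an additive screen and recover planted gamma", {
  lib <- makeLibrary(5, 3, 2)
  dd <- buildDualDesign(lib)
  genes <- targetGenes(lib)
  f <- setNames(c(-1, 0.5, 0, -0.25, 1), genes)
  sim0 <- noiselessSim(lib, dd, f = f)
  lfc0 <- constructLfc(sim0$counts, dd, pseudocount = 0)
  fit0 <- singleGeneFitness(lfc0, dd, lib)
  for (sc in list(slScoreHorlbeck(lfc0, fit0, dd),
                  slScoreMedian(lfc0, fit0, dd, TRUE),
                  slScoreMedian(lfc0, fit0, dd, FALSE),
                  slScoreSgrnaDerived(lfc0, fit0, dd, TRUE),
                  slScoreSgrnaDerived(lfc0, fit0, dd, FALSE)))
    expect_lt(max(abs(sc$score)), 1e-9)

  pair <- paste(sort(genes[c(1, 4)]), collapse = "__")
  simg <- noiselessSim(lib, dd, gamma = setNames(-2, pair), f = f)
  lfcg <- constructLfc(simg$counts, dd, pseudocount = 0)
  fitg <- singleGeneFitness(lfcg, dd, lib)
  sc <- slScores(lfcg, fitg, dd)
  i <- which(sc$pair == pair)
  expect_equal(sc$horlbeck[i], -2, tolerance = 1e-9)
  expect_equal(sc$median[i], -2, tolerance = 1e-9)
  expect_equal(sc$sgrna[i], -2, tolerance = 1e-9)
  expect_equal(which.min(sc$rra), i)
  expect_equal(sc$n_constructs[i], 18L)
})

test_that("Horlbeck pair score equals the explicit 18-construct enumeration", {
  lib <- makeLibrary(4, 3, 2)
  dd <- buildDualDesign(lib)
  set.seed(14)
  sim <- simulateCdkoScreen(dd, lib, screenTruth(depth = 300), 2, seed = 14)
  lfc <- constructLfc(normalizeCounts(sim$counts, safeSafeConstructs(dd)), dd)
  fit <- singleGeneFitness(lfc, dd, lib)
  sc <- slScoreHorlbeck(lfc, fit, dd)
  ct <- constructTable(dd)
  pair <- sc$pair[2]
  genes <- strsplit(pair, "__")[[1]]
  # brute force: loop every construct, collect deltas for this pair
  deltas <- c()
  for (r in seq_len(nrow(ct))) {
    gs <- c(ct$gene1[r], ct$gene2[r])
    if (setequal(gs, genes)) {
      deltas <- c(deltas, lfc[[ct$construct_id[r]]] -
                    fit$f_gene[[gs[1]]] - fit$f_gene[[gs[2]]])
    }
  }
  expect_equal(length(deltas), 18)
  expect_equal(sc$score[sc$pair == pair], mean(deltas), tolerance = 1e-12)
})

test_that("background normalization gives shift invariance, NB variants shift", {
  lib <- makeLibrary(4, 2, 2)
  dd <- buildDualDesign(lib)
  sim <- noiselessSim(lib, dd)
  lfc <- constructLfc(sim$counts, dd, pseudocount = 0)
  fit <- singleGeneFitness(lfc, dd, lib)
  b <- 0.7  # constant artifact added to every construct LFC
  lfc_s <- lfc + b
  fit_s <- singleGeneFitness(lfc_s, dd, lib)
  # guide fitness absorbs the shift once; deltas pick up -b net
  mB <- slScoreMedian(lfc, fit, dd, TRUE)
  mB_s <- slScoreMedian(lfc_s, fit_s, dd, TRUE)
  expect_equal(mB_s$score, mB$score, tolerance = 1e-9)
  mNB <- slScoreMedian(lfc, fit, dd, FALSE)
  mNB_s <- slScoreMedian(lfc_s, fit_s, dd, FALSE)
  expect_equal(mNB_s$score, mNB$score - b, tolerance = 1e-9)
  sB <- slScoreSgrnaDerived(lfc, fit, dd, TRUE)
  sB_s <- slScoreSgrnaDerived(lfc_s, fit_s, dd, TRUE)
  expect_equal(sB_s$score, sB$score, tolerance = 1e-9)
})

test_that("scores are invariant to swapping cassette positions", {
  lib <- makeLibrary(4, 2, 2)
  dd <- buildDualDesign(lib)
  set.seed(3)
  sim <- simulateCdkoScreen(dd, lib, screenTruth(depth = 300), 2, seed = 3)
  norm <- normalizeCounts(sim$counts, safeSafeConstructs(dd))
  lfc <- constructLfc(norm, dd)
  fit <- singleGeneFitness(lfc, dd, lib)
  sc <- slScores(lfc, fit, dd)
  # relabel: guide1 <-> guide2 for every construct = permuted lfc vector
  ct <- constructTable(dd)
  swapped <- setNames(lfc, paste0(ct$guide2[match(names(lfc), ct$construct_id)],
                                  "~",
                                  ct$guide1[match(names(lfc), ct$construct_id)]))
  fit_sw <- singleGeneFitness(swapped, dd, lib)
  sc_sw <- slScores(swapped, fit_sw, dd)
  expect_equal(sc_sw$horlbeck, sc$horlbeck, tolerance = 1e-12)
  expect_equal(sc_sw$median, sc$median, tolerance = 1e-12)
  expect_equal(sc_sw$sgrna, sc$sgrna, tolerance = 1e-12)
  expect_equal(sc_sw$rra, sc$rra, tolerance = 1e-12)
})

test_that("guide-level fitness corrects an outlier guide the gene median keeps", {
  # two genes x three guides; one guide of gene A is a fitness outlier, so
  # the gene median (-0.5) and the guide-level values diverge
  lib <- makeLibrary(2, 3, 1)
  dd <- buildDualDesign(lib)
  ct <- constructTable(dd)
  f_guide <- c(g0001 = -0.5, g0002 = -0.5, g0003 = -2.5,
               g0004 = 0.3, g0005 = 0.3, g0006 = 0.3, s01 = 0)
  lfc <- setNames(unname(f_guide[ct$guide1] + f_guide[ct$guide2]),
                  ct$construct_id)
  fit <- singleGeneFitness(lfc, dd, lib)
  sg <- slScoreSgrnaDerived(lfc, fit, dd, FALSE)
  expect_lt(max(abs(sg$score)), 1e-12)       # guide-resolution: unbiased
  h <- slScoreHorlbeck(lfc, fit, dd)
  expect_gt(max(abs(h$score)), 0.1)          # gene-median fitness: biased
})

test_that("the rank-aggregation rho matches the exhaustive small-case oracle", {
  # 5 pairs x 2 constructs with hand-made deltas: pair1 holds the 2 smallest
  lib <- makeLibrary(5, 1, 1)
  dd <- buildDualDesign(lib)
  ct <- constructTable(dd)
  genes <- targetGenes(lib)
  lfc <- setNames(numeric(nrow(ct)), ct$construct_id)
  distinct <- ct$gene1 != SAFE_GENE & ct$gene2 != SAFE_GENE &
    ct$gene1 != ct$gene2
  set.seed(33)
  lfc[distinct] <- rnorm(sum(distinct), 0, 0.1)
  p1 <- paste(sort(genes[1:2]), collapse = "__")
  lfc[distinct & ct$pair_unordered == p1] <- -5
  fit <- singleGeneFitness(lfc, dd, lib)  # all zero: safe pairings untouched
  rr <- slScoreRankAgg(lfc, fit, dd)
  expect_equal(rr$pair[which.min(rr$rho)], p1)
  # independent oracle: explicit percentile ranks + min Beta CDF per pair
  deltas <- lfc[ct$construct_id[distinct]]
  pct <- rank(deltas, ties.method = "average") / length(deltas)
  for (p in rr$pair) {
    mine <- pct[ct$pair_unordered[distinct] == p]
    expect_equal(rr$rho[rr$pair == p], rraRhoBrute(mine), tolerance = 1e-12)
  }
})

test_that("rank-aggregation permutation p-values are uniform on random input", {
  lib <- makeLibrary(8, 2, 1)
  dd <- buildDualDesign(lib)
  ct <- constructTable(dd)
  set.seed(41)
  lfc <- setNames(rnorm(nrow(ct), 0, 1), ct$construct_id)
  fit <- list(f_guide = setNames(numeric(nGuides(lib)), guideIds(lib)),
              f_gene = setNames(numeric(nGenes(lib) + 1),
                                c(targetGenes(lib), SAFE_GENE)))
  rr <- slScoreRankAgg(lfc, fit, dd, n_permutations = 400, seed = 2)
  ks <- suppressWarnings(ks.test(rr$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("consensus flags the shared top decile and is monotone in min_methods", {
  set.seed(6)
  n <- 100
  shared <- rnorm(n)
  sc <- data.frame(pair = sprintf("P%03d", 1:n),
                   horlbeck = shared, median = shared,
                   sgrna = shared, rra = rank(shared) / n)
  cons <- consensusSlPairs(sc)
  top <- sc$pair[order(shared)][1:10]
  expect_setequal(cons$consensus, top)

  # pair in the decile of exactly 3 of 4 methods is in; 2 of 4 is out
  sc2 <- data.frame(pair = c("X", "Y", sprintf("P%03d", 1:98)),
                    horlbeck = c(-10, -10, rnorm(98)),
                    median = c(-10, -10, rnorm(98)),
                    sgrna = c(-10, 10, rnorm(98)),
                    rra = c(0.99, 0.99, runif(98)))
  cons2 <- consensusSlPairs(sc2)
  expect_true("X" %in% cons2$consensus)
  expect_false("Y" %in% cons2$consensus)
  tab <- cons2$table
  expect_equal(tab$n_methods_hit[tab$pair == "X"], 3L)

  # monotone: raising min_methods never adds pairs
  for (mm in 2:4) {
    lo <- consensusSlPairs(sc2, min_methods = mm - 1)$consensus
    hi <- consensusSlPairs(sc2, min_methods = mm)$consensus
    expect_true(all(hi %in% lo))
  }
  expect_error(consensusSlPairs(sc2, top_fraction = 0), "0, 1")
})

test_that("candidate selection intersects the three criteria with Venn counts", {
  hall <- sprintf("H%03d", 1:80)
  expr <- setNames(c(rep(100, 70), rep(49, 10), rep(100, 20)),
                   c(hall, sprintf("X%03d", 1:20)))
  beta <- data.frame(gene = names(expr), condition = "control",
                     beta = c(rep(0, 65), rep(3, 5), rep(0, 10), rep(0, 20)),
                     p_value = 0.5, fdr = 0.5)
  res <- selectCdkoCandidates(hall, expr, beta)
  # engineered: 65 hallmark genes expressed > 50 and within the null band
  expect_equal(length(res$genes), 65)
  expect_setequal(res$genes, hall[1:65])
  # expression exactly 49 fails "above 50"; boundary 50 would too
  expect_false(any(hall[71:80] %in% res$genes))
  # a gene failing only the hallmark criterion lands in the right region
  expect_equal(unname(res$venn["expressed+nonessential"]), 20L)
  expect_equal(unname(res$venn["hallmark+expressed+nonessential"]), 65L)
})

test_that("network hubs match a brute-force degree count", {
  star <- paste0("HUB__N", 1:12)
  net <- slNetworkHubs(star, hub_threshold = 10)
  expect_equal(net$hubs, "HUB")
  expect_equal(unname(net$degrees["HUB"]), 12)

  empty <- slNetworkHubs(character(0))
  expect_equal(length(empty$hubs), 0)

  set.seed(77)
  genes <- sprintf("G%02d", 1:40)
  pairs <- unique(replicate(400, paste(sort(sample(genes, 2)),
                                       collapse = "__")))[1:242]
  net2 <- slNetworkHubs(pairs, hub_threshold = 10)
  # oracle: count incidences by hand
  flat <- unlist(strsplit(pairs, "__"))
  brute <- table(flat)
  expect_equal(sort(net2$degrees), sort(c(unclass(brute))),
               ignore_attr = TRUE)
  expect_setequal(net2$hubs, names(brute)[brute >= 10])
})
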