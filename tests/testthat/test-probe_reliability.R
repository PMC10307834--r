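test_that("influence windows match the published offset table", {
  w <- influence_window("F", "II")
  expect_equal(w$onsite, 0L)
  expect_equal(w$nt5, 1:5)
  expect_equal(w$nt10, 6:10)

  w <- influence_window("F", "I")
  expect_equal(w$onsite, c(-1L, 0L))
  expect_equal(w$nt5, 1:5)

  w <- influence_window("R", "I")
  expect_equal(w$onsite, c(1L, 2L))
  expect_equal(w$nt5, -4:0)
  expect_equal(w$nt10, -9:-5)

  w <- influence_window("R", "II")
  expect_equal(w$onsite, 1L)
})

test_that("windows are pairwise disjoint with union size 12 (I) / 11 (II)", {
  for (s in c("F", "R")) for (d in c("I", "II")) {
    w <- influence_window(s, d)
    all_off <- c(w$onsite, w$nt5, w$nt10)
    expect_equal(anyDuplicated(all_off), 0L)
    expect_length(all_off, if (d == "I") 12L else 11L)
  }
})

test_that("classify_snp resolves the documented example offsets", {
  p <- make_probe(strand = "F", design_type = "II", binding_pos = 1000L)
  expect_equal(classify_snp(p, make_snp(1000L)), "ONSITE")
  expect_true(is.na(classify_snp(p, make_snp(1011L))))  # offset 11

  pr <- make_probe(strand = "R", design_type = "II", binding_pos = 1000L)
  expect_equal(classify_snp(pr, make_snp(996L)), "NT5")  # offset -4

  expect_error(classify_snp(p, make_snp(1000L, chromosome = "7")),
               "different chromosomes")
})

test_that("classify_snp agrees exactly with the brute-force oracle", {
  # 1000 random probe/SNP fixtures spanning all 4 strand x design cases
  set.seed(42)
  n <- 1000L
  strands <- sample(c("F", "R"), n, replace = TRUE)
  designs <- sample(c("I", "II"), n, replace = TRUE)
  pos <- sample.int(1e6, n)
  offs <- sample(-15:15, n, replace = TRUE)
  for (i in seq_len(n)) {
    p <- make_probe(strand = strands[i], design_type = designs[i],
                    binding_pos = pos[i])
    got <- classify_snp(p, make_snp(pos[i] + offs[i]))
    want <- oracle_category(offs[i], strands[i], designs[i])
    expect_identical(got, want)
  }
})

test_that("strand mirroring (offset -> 1 - offset) preserves categories", {
  for (d in c("I", "II")) for (o in -15:15) {
    f <- hlameth:::classify_offset(o, "F", d)
    r <- hlameth:::classify_offset(1L - o, "R", d)
    expect_identical(f, r)
  }
})

test_that("audit_probe applies MAF thresholds and severity ordering", {
  p <- make_probe(strand = "F", design_type = "II", binding_pos = 1000L)
  # offsets 0 (maf .02) and 7 (maf .2): both hits at 0.01; only the .2
  # SNP clears 0.05; worst category is ONSITE
  snps <- rbind(make_snp(1000L, maf = 0.02), make_snp(1007L, maf = 0.2))
  a <- audit_probe(p, snps)
  expect_equal(a$n_hits, 2L)
  expect_equal(a$worst_category, "ONSITE")
  expect_true(a$unreliable_at_05)
  expect_true(a$unreliable_at_01)

  # below both MAF cuts: no hits at all
  a2 <- audit_probe(p, make_snp(1003L, maf = 0.005))
  expect_equal(a2$n_hits, 0L)
  expect_false(a2$unreliable_at_01)

  # no SNPs within +/-10
  a3 <- audit_probe(p, make_snp(2000L, maf = 0.3))
  expect_equal(a3$n_hits, 0L)
  expect_true(is.na(a3$worst_category))
})

test_that("audit_probe matches a brute-force scan on random panels", {
  set.seed(99)
  for (rep in 1:50) {
    p <- make_probe(strand = sample(c("F", "R"), 1),
                    design_type = sample(c("I", "II"), 1),
                    binding_pos = 5000L)
    snps <- make_snp(5000L + sample(-15:15, 8), maf = round(runif(8, 0.001, 0.5), 3))
    a <- audit_probe(p, snps)
    want <- vapply(seq_len(nrow(snps)), function(i)
      oracle_category(snps$position[i] - 5000L, p$strand, p$design_type),
      character(1))
    keep <- !is.na(want) & snps$maf >= 0.01
    expect_equal(a$n_hits, sum(keep))
    expect_setequal(a$hits$position, snps$position[keep])
    if (any(keep)) {
      sev <- c(ONSITE = 3, NT5 = 2, NT10 = 1)
      expect_equal(sev[[a$worst_category]], max(sev[want[keep]]))
    }
  }
})

test_that("audit_all recovers planted per-category counts", {
  # 10 forward Type II probes far apart; plant SNPs so exactly 3 probes
  # are ONSITE-hit, 2 NT5-hit, 1 NT10-hit
  probes <- do.call(rbind, lapply(1:10, function(i)
    make_probe(sprintf("cg%02d", i), binding_pos = i * 1000L)))
  snps <- rbind(
    make_snp(1000L, 0.2), make_snp(2000L, 0.2), make_snp(3000L, 0.2),
    make_snp(4003L, 0.2), make_snp(5001L, 0.2),
    make_snp(6008L, 0.2))
  a <- audit_all(probes, snps)
  s <- a$summary[a$summary$maf_threshold == 0.01, ]
  expect_equal(s$n_onsite_probes, 3L)
  expect_equal(s$n_nt5_probes, 2L)
  expect_equal(s$n_nt10_probes, 1L)
  expect_equal(s$n_unreliable, 6L)
})

test_that("audit_all counts multi-SNP probes within 10nt and within 5nt", {
  probes <- rbind(make_probe("cgA", binding_pos = 1000L),
                  make_probe("cgB", binding_pos = 9000L))
  # cgA: two hits in NT5; cgB: one NT5 + one NT10
  snps <- rbind(make_snp(1002L, 0.1), make_snp(1004L, 0.1),
                make_snp(9003L, 0.1), make_snp(9008L, 0.1))
  s <- audit_all(probes, snps)$summary
  s01 <- s[s$maf_threshold == 0.01, ]
  expect_equal(s01$n_multi_snp_10nt, 2L)
  expect_equal(s01$n_multi_snp_5nt, 1L)
})

test_that("empty panel leaves every probe reliable", {
  probes <- do.call(rbind, lapply(1:5, function(i)
    make_probe(sprintf("cg%02d", i), binding_pos = i * 100L)))
  a <- audit_all(probes, make_snp(integer(0)))
  expect_equal(sum(a$probes$n_hits), 0L)
  expect_true(all(a$summary$n_unreliable == 0L))
  expect_length(audit_blocklist(a), 0L)
})

test_that("unreliable set at MAF>=0.05 is a subset of the set at >=0.01", {
  set.seed(7)
  spec <- simulation_spec(n_probes = 300L, n_background_snps = 400L, seed = 11L)
  sim <- simulate_study(spec)
  a <- audit_all(sim$manifest, sim$snps)
  at05 <- a$probes$probe_id[a$probes$unreliable_at_05]
  at01 <- a$probes$probe_id[a$probes$unreliable_at_01]
  expect_true(all(at05 %in% at01))
  s <- a$summary
  expect_true(all(s[s$maf_threshold == 0.05, -1] <= s[s$maf_threshold == 0.01, -1]))
})

test_that("no SNP gets two categories for one probe", {
  set.seed(13)
  spec <- simulation_spec(n_probes = 200L, n_background_snps = 300L, seed = 13L)
  sim <- simulate_study(spec)
  a <- audit_all(sim$manifest, sim$snps)
  if (nrow(a$hits)) {
    key <- paste(a$hits$probe_id, a$hits$position)
    expect_equal(anyDuplicated(key), 0L)
  }
})

test_that("positional histogram bins flagged probes at 100 kb", {
  probes <- rbind(make_probe("cgA", binding_pos = 26050000L),
                  make_probe("cgB", binding_pos = 26060000L),
                  make_probe("cgC", binding_pos = 26150000L))
  snps <- rbind(make_snp(26050000L, 0.2), make_snp(26060000L, 0.2),
                make_snp(26150000L, 0.2))
  h <- audit_all(probes, snps)$histogram
  h01 <- h[h$maf_threshold == 0.01, ]
  expect_equal(h01$bin_start, c(26000000L, 26100000L))
  expect_equal(h01$n_probes, c(2L, 1L))
})
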