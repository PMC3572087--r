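test_that("encoder dimensionalities match the scheme contract", {
  dims <- scheme_dimensions(15)
  expect_identical(unname(dims[c("single_aa", "reduced_comp", "pair_aa",
                                 "triplet_aa", "binary_profile",
                                 "biprofile_bayes", "physchem")]),
                   c(20L, 10L, 400L, 8000L, 300L, 30L, 10L))
  # the reversal-merged class count comes from enumeration, and equals the
  # closed form: palindromic-endpoint triplets are singleton classes
  canon <- canonical_triplet_map()
  expect_length(canon, 8000)
  n_self <- sum(names(canon) == vapply(names(canon), function(t)
    paste(rev(strsplit(t, "")[[1]]), collapse = ""), character(1)))
  expect_identical(length(unique(canon)), (8000L - n_self) %/% 2L + n_self)
  expect_identical(length(canonical_triplet_classes()),
                   length(unique(canon)))
})

test_that("single amino acid composition is the per-residue frequency", {
  v <- encode_single("AAAAAAAAAAAAAAA")
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)

  pep <- "HLGYVLTCPSNLGTG"
  v2 <- encode_single(pep)
  counts <- table(strsplit(pep, "")[[1]])  # independent hand-count
  for (a in names(counts)) {
    expect_equal(unname(v2[a]), unname(counts[a]) / 15)
  }
  expect_equal(unname(v2["G"]), 3 / 15)
  expect_equal(unname(v2["L"]), 3 / 15)
  expect_error(encode_single("AXAAAAAAAAAAAAA"), "non-standard")
})

test_that("reduced composition blocks follow the class memberships and sum to 1", {
  v <- encode_reduced_comp("CCCCCCCCCCCCCCC")
  expect_equal(unname(v[1:3]), c(0, 0, 1))   # C is hydrophobic
  expect_equal(unname(v["sulfur"]), 1)

  pep <- "HLGYVLTCPSNLGTG"
  v2 <- encode_reduced_comp(pep)
  # independent tally against the published memberships
  ra <- reduced_alphabets()
  chars <- strsplit(pep, "")[[1]]
  for (cls in names(ra$classes3)) {
    expect_equal(unname(v2[cls]), sum(chars %in% ra$classes3[[cls]]) / 15)
  }
  expect_equal(unname(v2[c("polar", "neutral", "hydrophobic")]),
               c(1 / 15, 9 / 15, 5 / 15))
  expect_equal(sum(v2[1:3]), 1)
  expect_equal(sum(v2[4:10]), 1)
})

test_that("pair and triplet compositions agree with a k-mer counting oracle", {
  expect_equal(unname(encode_pair("AAAAAAAAAAAAAAA")["AA"]), 1)
  expect_equal(unname(encode_triplet("AAAAAAAAAAAAAAA")["AAA"]), 13)

  peps <- random_windows(50, seed = 21)
  for (pep in peps) {
    p2 <- encode_pair(pep)
    expect_equal(sum(p2), 1)
    oracle2 <- count_kmers(pep, 2)
    expect_equal(p2[names(oracle2)], as.vector(oracle2) / 14,
                 ignore_attr = TRUE)

    p3 <- encode_triplet(pep)
    expect_equal(sum(p3), 13)
    oracle3 <- count_kmers(pep, 3)
    expect_equal(p3[names(oracle3)], as.vector(oracle3),
                 ignore_attr = TRUE)
  }
})

test_that("reversal merging is symmetric and aggregates the full triplet counts", {
  expect_error(encode_reduced_triplet("ABDABDABDABDABD"), "non-standard")

  # ADW and WDA increment the same feature
  x1 <- encode_reduced_triplet("ADW")
  x2 <- encode_reduced_triplet("WDA")
  expect_identical(x1, x2)

  peps <- random_windows(50, seed = 22)
  canon <- canonical_triplet_map()
  for (pep in peps) {
    rt <- encode_reduced_triplet(pep)
    expect_equal(sum(rt), 13)
    rev_pep <- paste(rev(strsplit(pep, "")[[1]]), collapse = "")
    expect_identical(rt, encode_reduced_triplet(rev_pep))
    # aggregation oracle: summing full triplet counts within each class
    full <- encode_triplet(pep)
    agg <- tapply(full, canon[names(full)], sum)
    expect_equal(as.numeric(rt[names(agg)]), as.numeric(agg))
  }
  # plain triplet encoding is generally NOT reversal-symmetric
  pep <- "ADKLMCWCYVNPQRS"
  rev_pep <- paste(rev(strsplit(pep, "")[[1]]), collapse = "")
  expect_false(identical(encode_triplet(pep), encode_triplet(rev_pep)))
})

test_that("binary profile is one-hot per position with the alphabet order A,C,D,...,Y", {
  pep <- "HLGYVLTCPSNLGTG"
  v <- encode_binary(pep)
  expect_length(v, 300)
  expect_equal(sum(v), 15)
  # every 20-block has exactly one 1, at the residue's alphabet slot
  for (i in 1:15) {
    block <- v[((i - 1) * 20 + 1):(i * 20)]
    expect_equal(sum(block), 1)
    expect_equal(unname(which(block == 1)),
                 match(substr(pep, i, i), AA))
  }
  # the center block flags the cysteine slot (slot 2) on any valid window
  for (pep in random_windows(20, seed = 23)) {
    v <- encode_binary(pep)
    expect_equal(unname(v[7 * 20 + 2]), 1)
  }
})

test_that("bi-profile frequencies match a brute-force tally and rows sum to 1", {
  peps <- c("AAAAAAAAAAAAAAA", "AAAAAAACAAAAAAA")
  expect_error(fit_biprofile(peps, rep("positive", 2)), "negative")

  wd <- data.frame(peptide = random_windows(50, seed = 24),
                   label = rep(c("positive", "negative"), 25))
  prof <- fit_biprofile(wd$peptide, wd$label)
  expect_equal(unname(rowSums(prof$pos_freq)), rep(1, 15))
  expect_equal(unname(rowSums(prof$neg_freq)), rep(1, 15))
  # counting oracle at two arbitrary cells
  pos_peps <- wd$peptide[wd$label == "positive"]
  for (i in c(1, 9)) {
    for (a in c("A", "C")) {
      expect_equal(unname(prof$pos_freq[i, a]),
                   mean(substr(pos_peps, i, i) == a))
    }
  }
  # unanimous column with pseudocount 0
  two <- c("ACDEFGHCIKLMNPQ", "AYWVTSRCQPNMLKI")
  p2 <- fit_biprofile(rep(two, 2), c("positive", "negative",
                                     "positive", "negative"))
  expect_equal(unname(p2$pos_freq[1, "A"]), 1)
})

test_that("bi-profile encoding looks up per-position class frequencies", {
  wd <- data.frame(peptide = random_windows(30, seed = 25),
                   label = rep(c("positive", "negative"), 15))
  prof <- fit_biprofile(wd$peptide, wd$label)
  v <- encode_biprofile(wd$peptide[1], prof)
  expect_length(v, 30)
  expect_true(all(v >= 0 & v <= 1))
  # a window identical to the sole positive training window scores 1 on the
  # positive half
  solo <- fit_biprofile(c("AAAAAAACAAAAAAA", random_windows(1, seed = 26)),
                        c("positive", "negative"))
  v1 <- encode_biprofile("AAAAAAACAAAAAAA", solo)
  expect_equal(unname(v1[1:15]), rep(1, 15))
  expect_error(encode_biprofile("ACDC", prof), "length")
})

test_that("physicochemical sums are order-free and scale with composition", {
  tab <- load_property_table()
  expect_identical(dim(tab), c(20L, 10L))
  v <- encode_physchem("AAAAAAAAAAAAAAA", tab)
  expect_equal(unname(v), unname(15 * tab["A", ]))
  pep <- random_windows(1, seed = 27)
  shuf <- paste(sample(strsplit(pep, "")[[1]]), collapse = "")
  expect_equal(encode_physchem(pep, tab), encode_physchem(shuf, tab))
})

test_that("encode_windows builds labeled matrices for every scheme", {
  wd <- data.frame(protein_id = "p", center = 8L,
                   peptide = random_windows(12, seed = 28),
                   label = rep(c("positive", "negative"), 6))
  prof <- fit_biprofile(wd$peptide, wd$label)
  dims <- scheme_dimensions(15)
  for (scheme in names(dims)) {
    fm <- encode_windows(wd, scheme, profile = prof)
    expect_s3_class(fm, "feature_matrix")
    expect_identical(ncol(fm$features), unname(dims[scheme]))
    expect_identical(nrow(fm$features), 12L)
    expect_false(anyDuplicated(colnames(fm$features)) > 0)
  }
  # empty window set still yields a full-width header
  empty <- wd[0, ]
  fm0 <- encode_windows(empty, "binary_profile")
  expect_identical(dim(fm0$features), c(0L, 300L))
})
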