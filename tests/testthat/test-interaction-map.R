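glu_fixture <- function() {
  structure_from_atoms(tibble::tibble(
    atom = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
    resname = "GLU", chain = "A", resno = 64,
    x = c(-0.7, 0, -0.7, -1.9, 1.5, 2.9, 4.2, 4.9, 4.7),
    y = c(-1.2, 0, 1.2, 1.4, 0, 0.2, 0, 1.0, -1.1),
    z = 0
  ))
}

test_that("perceive_sites applies the residue rule table", {
  sites <- perceive_sites(glu_fixture())
  acc <- sites[sites$kind == "acceptor", ]
  expect_true(all(c("OE1", "OE2", "O") %in% acc$atom))
  expect_true("N" %in% sites$atom[sites$kind == "donor"])
  # directions are unit vectors where present
  with_dir <- sites[!is.na(sites$dx), ]
  norms <- sqrt(with_dir$dx^2 + with_dir$dy^2 + with_dir$dz^2)
  expect_true(all(abs(norms - 1) < 1e-6))
  # glycine: backbone donor and acceptor only, no hydrophobic site
  gly <- structure_from_atoms(tibble::tibble(
    atom = c("N", "CA", "C", "O"), resname = "GLY", chain = "A", resno = 1,
    x = c(0, 1.45, 2.1, 3.3), y = c(0, 0, 1.2, 1.3), z = 0
  ))
  gsites <- perceive_sites(gly)
  expect_setequal(gsites$kind, c("donor", "acceptor"))
  # empty input
  expect_equal(nrow(perceive_sites(fx_structure()[0, ])), 0)
})

test_that("complement_features projects, flips kind, and drops clashes", {
  s <- glu_fixture()
  pocket <- pocket_sphere(c(10, 0, 0), 12)
  sites <- perceive_sites(s)
  feats <- complement_features(sites, s, pocket, clash_dist = 1.5)
  # a protein acceptor generates a ligand-donor feature 2.9 A along its
  # direction
  oe1 <- sites[sites$atom == "OE1" & sites$kind == "acceptor", ]
  expected <- c(oe1$x, oe1$y, oe1$z) + 2.9 * c(oe1$dx, oe1$dy, oe1$dz)
  don <- feats[feats$kind == "donor", ]
  d <- sqrt((don$x - expected[1])^2 + (don$y - expected[2])^2 + (don$z - expected[3])^2)
  expect_true(any(d < 1e-9))
  # no feature may sit within clash_dist of a protein heavy atom
  hv <- tibble::as_tibble(s)
  for (i in seq_len(nrow(feats))) {
    dd <- sqrt((hv$x - feats$x[i])^2 + (hv$y - feats$y[i])^2 + (hv$z - feats$z[i])^2)
    expect_gte(min(dd), 1.5)
  }
  # every feature lies inside the pocket sphere
  dc <- sqrt((feats$x - 10)^2 + feats$y^2 + feats$z^2)
  expect_true(all(dc <= 12))
})

test_that("toy-pocket manifest sites are all perceived", {
  pock <- fx_pocket()
  sites <- perceive_sites(select_pocket(fx_structure(), fx_sphere()))
  found <- dplyr::semi_join(
    pock$manifest, sites,
    by = c("chain", "resno", "kind", "atom")
  )
  expect_equal(nrow(found), nrow(pock$manifest))
})

test_that("exclusion_volumes places one sphere per in-shell heavy atom", {
  s <- fx_structure()
  sph <- fx_sphere()
  ex0 <- exclusion_volumes(s, sph, margin = 0)
  ex5 <- exclusion_volumes(s, sph, margin = 5)
  expect_lte(nrow(ex0), nrow(ex5))
  # brute-force distance oracle at margin 2
  ex2 <- exclusion_volumes(s, sph, margin = 2)
  df <- tibble::as_tibble(s)
  df <- df[!df$element %in% c("H", "D"), ]
  d <- sqrt(df$x^2 + df$y^2 + df$z^2)
  expect_equal(nrow(ex2), sum(d <= sph$radius + 2))
  expect_true(all(ex2$radius == 1.4))
  expect_error(exclusion_volumes(s, sph, margin = -1))
})

feat_at <- function(kind, x, y = 0, z = 0) {
  tibble::tibble(
    kind = kind, x = x, y = y, z = z,
    dx = NA_real_, dy = NA_real_, dz = NA_real_,
    tolerance = 1.5, weight = 1, provenance = list(character())
  )
}

test_that("cluster_features merges by complete linkage per kind", {
  # two coincident acceptors merge with weight 2
  f <- dplyr::bind_rows(feat_at("acceptor", 1, 2, 3), feat_at("acceptor", 1, 2, 3))
  cl <- cluster_features(f, 1.5)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$weight, 2)
  expect_equal(c(cl$x, cl$y, cl$z), c(1, 2, 3))
  # two acceptors 10 A apart stay distinct
  f2 <- dplyr::bind_rows(feat_at("acceptor", 0), feat_at("acceptor", 10))
  expect_equal(nrow(cluster_features(f2, 1.5)), 2)
  # kinds never merge even when coincident
  f3 <- dplyr::bind_rows(feat_at("acceptor", 0), feat_at("donor", 0))
  expect_equal(nrow(cluster_features(f3, 1.5)), 2)
  expect_error(cluster_features(f3, 0))
})

test_that("collinear five-point case matches the complete-linkage oracle", {
  xs <- c(0, 1, 2, 8, 9)
  f <- dplyr::bind_rows(lapply(xs, function(x) feat_at("acceptor", x)))
  f$provenance <- lapply(seq_along(xs), as.character)
  cl <- cluster_features(f, 2.5)
  got <- partition_from_clusters(cl, 5)
  oracle <- oracle_iterated_linkage(as.matrix(f[, c("x", "y", "z")]), 2.5)
  expect_equal(got, oracle)
  expect_equal(sort(purrr::map_int(got, length)), c(2L, 3L))
})

test_that("clustering is idempotent and conserves total weight", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      f <- random_features(10)
      f$provenance <- lapply(seq_len(10), as.character)
      cl <- cluster_features(f, 2.0)
      expect_equal(sum(cl$weight), 10)
      cl2 <- cluster_features(cl, 2.0)
      expect_equal(nrow(cl2), nrow(cl))
      expect_equal(sort(cl2$x), sort(cl$x), tolerance = 1e-12)
    }
  })
})

test_that("enumerate_hypotheses counts subsets and honours min_pair_dist", {
  withr::with_seed(7, {
    f <- random_features(7, span = 20)
  })
  # make all pairs comfortably separated
  f$x <- f$x * 10; f$y <- f$y * 10; f$z <- f$z * 10
  h <- enumerate_hypotheses(f, kmin = 3, kmax = 7, min_pair_dist = 0)
  expect_equal(nrow(h), choose(7, 3) + choose(7, 4) + choose(7, 5) + choose(7, 6) + choose(7, 7))
  expect_equal(nrow(h), 99)
  # ids are sorted indices joined by '-' in lexicographic order
  expect_equal(h$id[1], "1-2-3")
  expect_false(is.unsorted(h$size))
  # every hypothesis feature is a member of the input list
  expect_true(all(unlist(h$idx) %in% seq_len(7)))
})

test_that("pair-distance constraint matches brute-force subset enumeration", {
  f <- dplyr::bind_rows(
    feat_at("donor", 0), feat_at("acceptor", 0.5), feat_at("hydrophobic", 8)
  )
  h <- enumerate_hypotheses(f, kmin = 3, kmax = 3, min_pair_dist = 2)
  # the 0.5 A pair invalidates the only size-3 subset
  expect_equal(nrow(h), 0)
  # brute force over all subsets of random features
  withr::with_seed(11, {
    f2 <- random_features(6, span = 3)
  })
  h2 <- enumerate_hypotheses(f2, kmin = 3, kmax = 4, min_pair_dist = 2.5)
  d <- as.matrix(dist(as.matrix(f2[, c("x", "y", "z")])))
  brute <- 0
  for (k in 3:4) {
    cmb <- utils::combn(6, k)
    for (j in seq_len(ncol(cmb))) {
      sub <- d[cmb[, j], cmb[, j]]
      if (all(sub[upper.tri(sub)] >= 2.5)) brute <- brute + 1
    }
  }
  expect_equal(nrow(h2), brute)
  # fewer features than kmin
  expect_warning(h3 <- enumerate_hypotheses(f2[1:2, ], kmin = 3, kmax = 7, min_pair_dist = 0))
  expect_equal(nrow(h3), 0)
})

test_that("interaction maps serialize and round-trip at 6 decimals", {
  m <- fx_map()
  path <- withr::local_tempfile(fileext = ".json")
  write_map(m, path)
  m2 <- read_map(path)
  expect_equal(round(m2$features$x, 6), round(m$features$x, 6))
  expect_equal(round(m2$features$tolerance, 6), round(m$features$tolerance, 6))
  expect_equal(m2$features$kind, m$features$kind)
  expect_equal(m2$features$provenance, m$features$provenance)
  expect_equal(round(m2$exclusions$x, 6), round(m$exclusions$x, 6))
  expect_equal(m2$pocket$radius, m$pocket$radius)
  # writing the reread map reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".json")
  write_map(m2, path2)
  expect_identical(readLines(path), readLines(path2))
})
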