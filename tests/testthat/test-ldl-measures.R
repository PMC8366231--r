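test_that("word paths are the word's own overlapping triphone sequence", {
  cues <- c("#k{", "k{t", "{t#", "#a#")
  p <- word_path("k{t", cues)
  expect_identical(p, c("#k{", "k{t", "{t#"))
  # consecutive nodes overlap in two symbols
  expect_true(all(substr(p[-1], 1, 2) == substr(p[-length(p)], 2, 3)))
  expect_identical(word_path("a", cues), "#a#")
  expect_error(word_path("ka", cues), "missing")

  six <- paste(rep(c("t", "a"), 3), collapse = "")
  p6 <- word_path(six, to_triphones(six))
  expect_length(p6, 6L)
})

test_that("node supports normalize over left-context competitor sets", {
  # competitors share the two-symbol left context of the node
  cues <- c("#ka", "#ko", "kat", "kab")
  # sole positive competitor in its "#k" context: support 1
  act <- c("#ka" = 2, "#ko" = 0, "kat" = 0.5, "kab" = 0.5)
  s <- node_supports(c("#ka", "kat"), act, cues)
  expect_equal(unname(s[1]), 1.0)
  # two equal positive competitors in "ka": each 0.5
  expect_equal(unname(s[2]), 0.5)
  # negatives clamp to zero; an all-negative context yields support 0
  act2 <- c("#ka" = -1, "#ko" = -2, "kat" = 1, "kab" = 3)
  s2 <- node_supports(c("#ka", "kat"), act2, cues)
  expect_equal(unname(s2), c(0, 0.25))
})

test_that("supports on a fitted network are probabilities per competitor set", {
  study <- small_study()
  net <- study$networks$morphology
  cues <- colnames(net$C)
  left <- substr(cues, 1, 2)
  for (id in rownames(net$C)[1:20]) {
    act <- pmax(net$C_hat[id, ], 0)
    sums <- tapply(act, left, sum)
    word <- study$lexicon$transcription[study$lexicon$word_id == id]
    s <- node_supports(word_path(word, cues), net$C_hat[id, ], cues)
    expect_true(all(s >= 0 & s <= 1))
    # where any positive activation exists, supports over a competitor
    # set sum to 1
    for (ctx in unique(substr(names(s), 1, 2))) {
      if (sums[[ctx]] > 0) {
        in_ctx <- cues[left == ctx]
        expect_equal(sum(act[in_ctx] / sums[[ctx]]), 1.0)
      }
    }
  }
})

test_that("path sum and mean word support follow their worked definitions", {
  expect_equal(path_sum(rep(1, 5)), 5)
  expect_equal(path_sum(c(0, 0, 0)), 0)
  expect_equal(path_sum(c(0.2, 0.3)), 0.5)
  expect_error(path_sum(numeric(0)), "empty")

  expect_equal(mean_word_support(rep(1, 5)), 1.0)
  expect_equal(mean_word_support(rep(0.4, 7)), 0.4)
  # length invariance: perfectly supported words of different lengths tie
  expect_equal(mean_word_support(rep(1, 3)), mean_word_support(rep(1, 8)))
  # transition divisor variant
  expect_equal(mean_word_support(rep(1, 5), divisor = "transitions"), 5 / 4)
})

test_that("path entropy is Shannon entropy of the normalized supports", {
  expect_equal(path_entropy(c(0.5, 0.5)), 1.0)
  expect_equal(path_entropy(1), 0.0)
  for (n in c(2, 4, 8)) expect_equal(path_entropy(rep(0.3, n)), log2(n))
  expect_true(is.na(path_entropy(c(0, 0))))
})

test_that("semantic vector length is the L1 norm", {
  expect_equal(semantic_vector_length(c(0, 0, 0)), 0)
  expect_equal(semantic_vector_length(c(0.3, -0.2, 0.5)), 1.0)
  v <- rnorm(20)
  expect_equal(semantic_vector_length(2 * v), 2 * semantic_vector_length(v))
})

test_that("target correlation is Pearson r with flagged degenerate cases", {
  v <- rnorm(10)
  expect_equal(target_correlation(v, v), 1.0)
  expect_equal(target_correlation(v, -v), -1.0)
  expect_true(is.na(target_correlation(rep(1, 10), v)))
  study <- small_study()
  expect_identical(qr(study$cue)$rank, nrow(study$cue))
  m <- study$measures$morphology
  # full-row-rank network: exact interpolation, r = 1 for every word
  expect_true(all(abs(m$target_correlation - 1) < 1e-8))
})

test_that("semantic density averages the top-k neighbor correlations", {
  set.seed(11)
  base <- rnorm(30)
  # 8 neighbors that are positive affine images of the target: density 1
  mat <- rbind(target = base,
               t(sapply(1:8, function(i) base * runif(1, 0.5, 2) + rnorm(1))),
               t(matrix(rnorm(60), 30, 2)))
  rownames(mat) <- c("target", paste0("n", 1:8), "r1", "r2")
  expect_equal(semantic_density("target", mat, k = 8), 1.0)

  # orthogonal high-dimensional noise: density near zero
  big <- matrix(rnorm(30 * 200), 30, 200,
                dimnames = list(paste0("w", 1:30), NULL))
  dens <- vapply(rownames(big), semantic_density, numeric(1), s_hat = big)
  expect_true(all(abs(dens) < 0.5) && abs(mean(dens)) < 0.2)

  expect_error(semantic_density("w1", big[1:5, ], k = 8), "at least")
})

test_that("shared category vectors raise density in richer architectures", {
  study <- small_study()
  dens_i <- mean(study$measures$idiosyncratic$semantic_density)
  dens_m <- mean(study$measures$morphology$semantic_density)
  expect_gt(dens_m, dens_i)
})

test_that("neighbor reports rank neighbors and count category diversity", {
  set.seed(12)
  base <- rnorm(200)
  mat <- rbind(matrix(rnorm(8 * 200), 8, 200), hub = base)
  # make every non-hub row lean toward the hub so the hub ranks first
  for (i in 1:8) mat[i, ] <- base + rnorm(200, sd = 0.2)
  rownames(mat) <- c(paste0("w", 1:8), "hub")
  lex <- tibble::tibble(word_id = rownames(mat),
                        transcription = paste0("t", letters[1:9]),
                        base_id = c(rep("hub", 8), NA),
                        category = c(rep("CAT", 8), NA))
  net <- list(S_hat = mat, S = mat)
  rep_ <- neighbor_report(net, lex, k = 8)
  first <- rep_$neighbors[rep_$neighbors$rank == 1 &
                            rep_$neighbors$word_id != "hub", ]
  expect_true(all(first$neighbor_id == "hub"))
  expect_true(all(rep_$neighbors$word_id != rep_$neighbors$neighbor_id))
  # diversity bound: at most k * members unique neighbor types
  expect_true(all(rep_$diversity$n_unique_neighbors <=
                    8 * rep_$diversity$n_members))
})

test_that("category information concentrates neighborhoods within categories", {
  # when the network encodes morphological categories, a larger share of a
  # derived word's top-8 neighbors comes from its own category
  study <- small_study()
  lex <- study$lexicon
  own_cat_share <- function(v) {
    nb <- neighbor_report(study$networks[[v]], lex)$neighbors
    cats <- stats::setNames(lex$category, lex$word_id)
    nb <- nb[!is.na(cats[nb$word_id]), ]
    mean(!is.na(cats[nb$neighbor_id]) &
           cats[nb$neighbor_id] == cats[nb$word_id])
  }
  expect_gt(own_cat_share("morphology"), own_cat_share("idiosyncratic"))
})

test_that("rank-sum comparison matches exact enumeration and controls type I", {
  expect_equal(compare_distributions(c(1, 2, 3), c(10, 11, 12)), 0.1)
  set.seed(13)
  x <- rnorm(30)
  expect_gt(compare_distributions(x, x), 0.99)
  rej <- mean(replicate(1000, {
    compare_distributions(rnorm(12), rnorm(12)) < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
  expect_error(compare_distributions(numeric(0), 1), "non-empty")
})

test_that("measure table respects its documented bounds", {
  study <- small_study()
  for (m in study$measures) {
    expect_true(all(m$mean_word_support >= 0 & m$mean_word_support <= 1))
    expect_true(all(m$path_entropies >= 0, na.rm = TRUE))
    expect_true(all(m$semantic_density >= -1 & m$semantic_density <= 1))
    expect_true(all(abs(m$target_correlation) <= 1 + 1e-12, na.rm = TRUE))
    expect_true(all(m$semantic_vector_length >= 0))
    n_nodes <- nchar(study$lexicon$transcription[
      match(m$word_id, study$lexicon$word_id)])
    expect_true(all(m$path_entropies <= log2(n_nodes) + 1e-9, na.rm = TRUE))
  }
})

test_that("category structure emerges even in the idiosyncratic network", {
  study <- small_study()
  m <- dplyr::inner_join(study$measures$idiosyncratic,
                         study$lexicon[, c("word_id", "category")],
                         by = "word_id")
  m <- m[!is.na(m$category), ]
  cats <- unique(m$category)
  ps <- combn(cats, 2, function(pair) {
    compare_distributions(m$semantic_density[m$category == pair[1]],
                          m$semantic_density[m$category == pair[2]])
  })
  # most category pairs separate even without category information
  expect_gt(mean(ps < 0.05), 0.5)
})
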