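white_tile <- function() array(255, c(256, 256, 3))

test_that("toy backbone is deterministic and translation-invariant on flat tiles", {
  bb <- backbone_toy()
  out1 <- embed_tile(bb, white_tile())
  out2 <- embed_tile(bb, white_tile())
  expect_identical(out1$cls, out2$cls)
  expect_identical(out1$patch_tokens, out2$patch_tokens)
  # all patches of a constant tile are identical
  expect_equal(max(abs(sweep(out1$patch_tokens, 2, out1$patch_tokens[1, ]))), 0)
})

test_that("constant tiles put zeros in the variance and gradient slots", {
  stats <- staincast:::patch_statistics(white_tile() / 255)
  expect_true(all(stats[, 4:9] == 0))               # sd and gradient slots
  expect_true(all(stats[, 1:3] == 1))               # channel means
})

test_that("permuting patch contents permutes patch tokens identically", {
  withr::with_seed(21, {
    tile <- array(runif(256 * 256 * 3) * 255, c(256, 256, 3))
    bb <- backbone_toy()
    tok <- embed_tile(bb, tile)$patch_tokens
    # swap patch blocks (0,0) and (2,3): indices k = 0 and k = 35
    tile2 <- tile
    tile2[1:16, 1:16, ] <- tile[33:48, 49:64, ]
    tile2[33:48, 49:64, ] <- tile[1:16, 1:16, ]
    tok2 <- embed_tile(bb, tile2)$patch_tokens
    expect_equal(tok2[1, ], tok[36, ])
    expect_equal(tok2[36, ], tok[1, ])
    others <- setdiff(1:256, c(1, 36))
    expect_equal(tok2[others, ], tok[others, ])
  })
})

test_that("projection matrices are reproducible across adapter instances", {
  z1 <- embed_tile(backbone_toy(seed = 7), white_tile())
  z2 <- embed_tile(backbone_toy(seed = 7), white_tile())
  z3 <- embed_tile(backbone_toy(seed = 8), white_tile())
  expect_identical(z1$cls, z2$cls)
  expect_false(identical(z1$cls, z3$cls))
})

test_that("declared dimensions are enforced on backbone output", {
  liar <- backbone("liar", d_local = 192, d_global = 384,
                   embed = function(a) list(cls = rep(0, 100),
                                            patch_tokens = matrix(0, 256, 192)))
  expect_error(embed_tile(liar, white_tile()), "d_global")
  liar2 <- backbone("liar2", d_local = 192, d_global = 384,
                    embed = function(a) list(cls = rep(0, 384),
                                             patch_tokens = matrix(0, 10, 192)))
  expect_error(embed_tile(liar2, white_tile()), "d_local")
  expect_error(embed_tile(backbone_toy(), array(0, c(64, 64, 3))), "256 x 256")
})

test_that("fusion is an exact mean over the selected patch tokens", {
  withr::with_seed(22, {
    tile <- array(runif(256 * 256 * 3) * 255, c(256, 256, 3))
    out <- embed_tile(backbone_toy(), tile)
    # mean of one: c1 equals that token exactly
    f1 <- fuse_features(out, 17L)
    expect_equal(f1$c1, out$patch_tokens[18, ])
    # brute-force sum / k
    idx <- sort(sample(0:255, 40))
    fz <- fuse_features(out, idx)
    brute <- colSums(out$patch_tokens[idx + 1, ]) / length(idx)
    expect_equal(fz$c1, brute, tolerance = 1e-12)
    # permutation invariance in the index list
    expect_identical(fuse_features(out, rev(idx))$z, fz$z)
    # dimension contract: 192 + 384 = 576
    expect_length(fz$z, 576)
    expect_identical(fz$z, c(fz$c1, fz$c2))
    # componentwise convex hull
    sel <- out$patch_tokens[idx + 1, ]
    expect_true(all(fz$c1 >= apply(sel, 2, min) - 1e-12))
    expect_true(all(fz$c1 <= apply(sel, 2, max) + 1e-12))
    expect_error(fuse_features(out, integer(0)), "empty")
    expect_error(fuse_features(out, 300L), "\\[0, 255\\]")
  })
})

test_that("embed_cells produces the declared layout and slices cleanly", {
  sl <- small_slide()
  feats <- embed_cells(sl$image, sl$polygons[1:5, ])
  expect_equal(dim(feats$z), c(5, 576))
  expect_equal(ncol(feature_slice(feats, "full")), 576)
  expect_equal(ncol(feature_slice(feats, "local_only")), 192)
  expect_equal(ncol(feature_slice(feats, "global_only")), 384)
  expect_identical(cbind(feature_slice(feats, "local_only"),
                         feature_slice(feats, "global_only")),
                   feats$z)
  expect_true(all(feats$cells$n_patches >= 1))
})
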