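test_that("distances and delays follow the spatial model", {
  expect_equal(euclidean_distance(0, -1, 1.6, -1), 1.6)
  expect_equal(euclidean_distance(5, -1, 5, 1), 2)
  expect_equal(euclidean_distance(0, -1, 1.6, 1), sqrt(1.6^2 + 4),
               tolerance = 1e-12)
  expect_equal(compute_delay(1.6, 0.8), 2)
  expect_equal(compute_delay(sqrt(1.6^2 + 4), 0.8), 3.2, tolerance = 0.01)
  expect_equal(compute_delay(0, 4), 0)
  expect_error(compute_delay(1, 0), "positive")
  # intersegmental swimming delays fall in the reported 3-4 ms band
  d <- compute_delay(euclidean_distance(0, -1, 1.6, 1), 0.8)
  expect_true(d >= 3 && d <= 4)
})

test_that("population counts match the model descriptions", {
  expect_equal(nrow(build_single_coiling()$neurons), 50)   # 2 x (5+10+10)
  expect_equal(nrow(build_double_coiling()$neurons), 90)   # 2 x (5+4x10)
  expect_equal(nrow(build_beat_and_glide("base")$neurons), 150)  # 2 x 5 x 15
})

test_that("every connection weight equals its table entry", {
  for (variant in c("single_coiling", "double_coiling", "beat_glide_base")) {
    sheet <- model_param_sheet(variant)
    circ <- switch(variant,
      single_coiling = build_single_coiling(),
      double_coiling = build_double_coiling(),
      beat_glide_base = build_beat_and_glide(
        "base", overrides = list(dI6_noise_sd = 0)))
    cn <- circ$connections
    nr <- circ$neurons
    gpj <- sheet$constants$gap_pair_junctions
    for (i in seq_len(nrow(cn))) {
      pre <- nr$kind[cn$pre[i]]; post <- nr$kind[cn$post[i]]
      if (cn$kind[i] == "gap") {
        key <- paste0(pre, "-", post)
        alt <- paste0(post, "-", pre)
        w <- sheet$gap_weights[[key]]
        if (is.null(w)) w <- sheet$gap_weights[[alt]]
        expect_equal(cn$weight[i], w * gpj,
                     info = paste(variant, key, "gap"))
      } else {
        key <- paste0(pre, "-", post)
        expect_equal(cn$weight[i], sheet$chem_weights[[key]],
                     info = paste(variant, key, cn$kind[i]))
      }
    }
  }
})

test_that("projection ranges clip at the body boundaries", {
  circ <- build_single_coiling()
  cn <- circ$connections; nr <- circ$neurons
  # V0d #1 projects glycinergic synapses to contralateral MNs 1-6 only
  v0d1 <- nr$id[nr$kind == "V0d" & nr$side == "left" & nr$index == 1]
  tgt <- cn[cn$pre == v0d1 & cn$kind == "gly" &
            nr$kind[cn$post] == "MN", ]
  expect_setequal(nr$index[tgt$post], 1:6)
  expect_true(all(nr$side[tgt$post] == "right"))
  # no connection references a nonexistent segment
  expect_true(all(nr$segment[cn$post] <= 10 | nr$kind[cn$post] == "IC"))
  # beat-and-glide: V2a #10 descending targets span segments 11-15 only
  bg <- build_beat_and_glide("base")
  v2a10 <- bg$neurons$id[bg$neurons$kind == "V2a" &
                         bg$neurons$side == "left" &
                         bg$neurons$index == 10]
  desc <- bg$connections[bg$connections$pre == v2a10 &
                         bg$connections$rule == "chem.V2a.V2a", ]
  expect_true(all(bg$neurons$segment[desc$post] %in% 11:15))
})

test_that("gap junctions are symmetric and coiling glycine crosses the midline", {
  for (circ in list(build_single_coiling(), build_double_coiling())) {
    cn <- circ$connections; nr <- circ$neurons
    gap <- cn[cn$kind == "gap", ]
    key <- paste(gap$pre, gap$post)
    rkey <- paste(gap$post, gap$pre)
    expect_true(all(rkey %in% key))  # both directions present
    # weights equal across directions
    w1 <- gap$weight[order(key)]
    w2 <- gap$weight[order(rkey)]
    expect_equal(w1, w2)
    # all glycinergic synapses in coiling models are contralateral
    gly <- cn[cn$kind == "gly", ]
    expect_true(all(nr$side[gly$pre] != nr$side[gly$post]))
    # delays always equal distance / cv
    expect_equal(cn$delay, cn$distance / circ$constants$cv)
  }
})

test_that("left and right connection sets are mirror images", {
  circ <- build_beat_and_glide("base", overrides = list(dI6_noise_sd = 0))
  cn <- circ$connections; nr <- circ$neurons
  lab <- function(id) paste0(nr$kind[id], nr$index[id])
  side <- nr$side[cn$pre]
  keyL <- sort(paste(lab(cn$pre), lab(cn$post), cn$kind,
                     signif(cn$weight, 10))[side == "left"])
  keyR <- sort(paste(lab(cn$pre), lab(cn$post), cn$kind,
                     signif(cn$weight, 10))[side == "right"])
  expect_identical(keyL, keyR)
})

test_that("dI6 commissural weights carry Gaussian(1, 0.1) scaling", {
  set.seed(42)
  circ <- build_beat_and_glide("base")
  w <- circ$connections$weight[circ$connections$rule == "chem.dI6.dI6"]
  base <- model_param_sheet("beat_glide_base")$chem_weights[["dI6-dI6"]]
  scale <- w / base
  expect_gt(stats::sd(scale), 0.05)
  expect_lt(abs(mean(scale) - 1), 3 * 0.1 / sqrt(length(scale)) + 0.02)
  expect_true(all(scale >= 0))
})

test_that("glycinergic reversal potential tracks development", {
  expect_equal(build_single_coiling()$constants$E_gly, -45)
  expect_equal(build_double_coiling()$constants$E_gly, -58)
  expect_equal(build_beat_and_glide("base")$constants$E_gly, -70)
})

test_that("overrides reach nested parameters and unknown paths fail", {
  circ <- build_single_coiling(overrides = list("constants.cv" = 2))
  expect_equal(circ$constants$cv, 2)
  expect_equal(circ$connections$delay, circ$connections$distance / 2)
  expect_error(build_single_coiling(overrides = list("nope.x" = 1)),
               "unknown override path")
})

test_that("connectome export lists every edge with labels", {
  circ <- build_single_coiling()
  edges <- export_connectome(circ)
  expect_equal(nrow(edges), nrow(circ$connections))
  expect_true(all(c("pre", "post", "kind", "weight", "delay") %in%
                  names(edges)))
  expect_match(edges$pre[1], "^(IC|MN|V0d)_[lr][0-9]+$")
})
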