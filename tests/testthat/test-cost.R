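test_that("raw media sizes follow the exact PCM arithmetic", {
  expect_equal(media_size(media_spec(60)), 5292000)     # ~5 MB per minute
  expect_equal(media_size(media_spec(5)), 441000)       # 44100 * 5 * 2
  expect_equal(media_size(media_spec(0)), 0)
  expect_equal(media_size(media_spec(5, bits_per_sample = 32)), 882000)
})

test_that("transmission time is payload- and rate-linear", {
  link <- link_spec(1000)
  expect_equal(tx_time(70, link), 0.56)                 # one result message
  expect_equal(tx_time(0, link), 0)
  expect_equal(tx_time(5e6, link), 40000)               # ~11 h model push
  # linearity in payload, inverse linearity in rate
  expect_equal(tx_time(140, link), 2 * tx_time(70, link))
  expect_equal(tx_time(70, link_spec(2000)), tx_time(70, link) / 2)
  # protocol overhead multiplies
  expect_equal(tx_time(70, link, overhead = 2), 1.12)
})

test_that("shipping raw 5-s audio over 1 kbps breaks real time", {
  rep <- centralized_latency(media_spec(5), link_spec(1000))
  expect_equal(rep$total_s, 441000 * 8 / 1000)          # 3528 s
  expect_false(rep$realtime_feasible)
  expect_equal(unname(rep$components["audio_tx"]), rep$total_s)
  # in the infinite-rate limit the transfer vanishes and becomes feasible
  fast <- centralized_latency(media_spec(5), link_spec(1e12))
  expect_lt(fast$total_s, 1e-3)
  expect_true(fast$realtime_feasible)
})

test_that("on-node classification plus a 70-B result is real-time", {
  rep <- distributed_latency(node_timing(), link_spec(1000))
  expect_equal(unname(rep$components),
               c(0.120, 0.160, 0.56))
  expect_equal(unname(rep$subtotals["processing"]), 0.28)
  expect_equal(rep$total_s, 0.84)
  expect_true(rep$realtime_feasible)
  # degenerate all-zero node: zero total
  zero <- distributed_latency(node_timing(0, 0, 0), link_spec(1000))
  expect_equal(zero$total_s, 0)
})

test_that("the distributed paradigm wins by orders of magnitude", {
  link <- link_spec(1000)
  cen <- centralized_latency(media_spec(5), link)
  dis <- distributed_latency(node_timing(), link)
  expect_gt(cen$total_s / dis$total_s, 1000)
})

test_that("model push times scale linearly and feasibility is rate-monotone", {
  link <- link_spec(1000)
  expect_equal(model_deploy_time(0, link), 0)
  expect_equal(model_deploy_time(2 * 5e6, link), 2 * model_deploy_time(5e6, link))
  # raising the link rate never flips feasible -> infeasible
  rates <- c(1e3, 1e4, 1e5, 1e6, 1e9)
  flags <- vapply(rates, function(r)
    centralized_latency(media_spec(5), link_spec(r))$realtime_feasible,
    logical(1))
  expect_true(all(diff(as.integer(flags)) >= 0))
})
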