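test_that("division summary reproduces the single-product reference rows", {
  profiles <- list(daaap_like_profile(), dhot_like_profile())
  s <- summarize_by_division(profiles)
  disp <- format_division_table(s)
  daaap <- disp[disp$division == "DAAAP", ]
  expect_equal(unname(unlist(daaap[c("n_products", "avg_gbs", "avg_rrs", "nbs", "brr")])),
               c(1, 100, -16, 84, 6.25))
  dhot <- disp[disp$division == "DHOT", ]
  expect_equal(unname(unlist(dhot[c("n_products", "avg_gbs", "avg_rrs", "nbs", "brr")])),
               c(1, 100, -31, 69, 3.23))
  # all-products row aggregates both
  all_row <- s[s$division == "All products", ]
  expect_equal(all_row$n_products, 2)
  expect_equal(all_row$mean_brr, mean(c(6.25, 3.23)))  # mean of ratios, not ratio of means
})

test_that("summary identities hold and duplicated products average to themselves", {
  pool <- random_pool()
  profiles <- pool[1:30]
  s <- summarize_by_division(profiles)
  expect_equal(s$nbs_of_means, s$mean_gbs + s$mean_rrs_signed, tolerance = 1e-9)
  expect_true(all(s$mean_rrs_signed <= 0))
  # permutation invariance
  perm <- summarize_by_division(profiles[c(17:30, 1:16)])
  expect_equal(s, perm)
  # two identical products give the same row as one, with n = 2
  twin <- list(daaap_like_profile(), daaap_like_profile())
  twin[[2]]$product_id <- "FIX-DAAAP-2"
  s1 <- summarize_by_division(twin[1])
  s2 <- summarize_by_division(twin)
  expect_equal(s2$n_products[s2$division == "DAAAP"], 2)
  expect_equal(s2$mean_gbs, s1$mean_gbs)
  expect_equal(s2$mean_brr, s1$mean_brr)
})

test_that("scatter data carries exact breakdown values with deterministic ordering", {
  profiles <- list(dhot_like_profile(), daaap_like_profile())
  bks <- score_portfolio(profiles)
  pts <- scatter_data(profiles, bks, group_by = "division")
  expect_equal(nrow(pts), 2)
  expect_equal(pts$group, sort(pts$group))
  for (i in seq_len(nrow(pts))) {
    b <- bks[[pts$product_id[i]]]
    expect_equal(pts$nbs[i], b$nbs)
    expect_equal(pts$brr[i], b$brr)
  }
  by_ind <- scatter_data(profiles, bks, group_by = "indication")
  expect_setequal(by_ind$group, c("chronic_pain", "hematologic_malignancy"))
})

test_that("milestone trajectories rescore each snapshot and respect mitigation monotonicity", {
  s1 <- daaap_like_profile()
  s2 <- s1
  s2$risks[[1]]$mitigations <- s1$risks[[1]]$mitigations[1]  # drop the registry
  s3 <- s1
  traj <- approval_trajectory(list(s2, s1, s3), labels = c("phase2", "bla", "approval"))
  expect_equal(traj$milestone, c("phase2", "bla", "approval"))
  # adding a mitigation between snapshots never lowers the net benefit
  expect_true(all(diff(traj$nbs) >= 0))
  expect_equal(traj$nbs[2], traj$nbs[3])  # identical snapshots, identical points
  b <- score_product(s1)
  expect_equal(traj$nbs[2], b$nbs)
  other <- dhot_like_profile()
  expect_error(approval_trajectory(list(s1, other)), class = "brscore_domain_error")
})

test_that("the structured report lays out benefit, per-risk and net-benefit rows", {
  p <- dhot_like_profile()
  b <- score_product(p)
  rep <- render_report(p, b)
  expect_equal(nrow(rep$rows), 4 + 2 + 1)
  expect_equal(rep$rows$decision_factor[5:6],
               c("Risk and Mitigations #1", "Risk and Mitigations #2"))
  expect_match(rep$rows$score[7], paste0("NBS ", b$nbs))
  # verbatim evidence text carried into the evidence column
  expect_match(rep$rows$evidence[6], "infusion reaction")
  # JSON serialization round-trips the content exactly
  rt <- parse_report_json(report_json(rep))
  expect_equal(rt, rep)
  md <- report_markdown(rep)
  expect_match(md, "\\| Net benefit \\|")
})
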