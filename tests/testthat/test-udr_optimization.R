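make_linear <- function(vals) expr_matrix(vals, scale = "linear")

test_that("UDR score evaluates the up/down mean ratio", {
  m <- make_linear(matrix(c(8, 2, 6), 3, 1,
                          dimnames = list(c("u1", "d1", "d2"), "S1")))
  p <- panel_assignment("u1", c("d1", "d2"))
  expect_equal(unname(udr_score(m, p)), 2)            # 8 / mean(2, 6)
  eq <- make_linear(matrix(5, 3, 2, dimnames = list(c("u1", "d1", "d2"),
                                                    c("S1", "S2"))))
  expect_equal(unname(udr_score(eq, p)), c(1, 1))
  # scale invariance under any positive rescaling
  expect_equal(udr_score(make_linear(unclass(m) * 10), p), udr_score(m, p))
  expect_equal(udr_score(make_linear(unclass(m) * 0.037), p), udr_score(m, p))
})

test_that("UDR contract: scales, membership, missingness", {
  m <- make_linear(matrix(c(8, 2, 6, NA, 4, 4), 3, 2,
                          dimnames = list(c("u1", "d1", "d2"), c("S1", "S2"))))
  p <- panel_assignment("u1", c("d1", "d2"))
  expect_warning(sc <- udr_score(m, p), "skipped")
  expect_true(is.na(sc[["S2"]]))
  expect_false(is.na(sc[["S1"]]))
  expect_error(udr_score(m, panel_assignment("u1", "ghost")), "ghost")
  counts <- expr_matrix(matrix(1:6, 3, 2,
                               dimnames = list(c("u1", "d1", "d2"),
                                               c("S1", "S2"))),
                        scale = "counts")
  expect_error(udr_score(counts, p), "linear")
  # log variant is the difference of mean log2 expressions
  v <- matrix(c(8, 2, 32), 3, 1, dimnames = list(c("u1", "d1", "d2"), "S1"))
  expect_equal(unname(udr_score(make_linear(v), p, type = "log")),
               3 - mean(c(1, 5)))
})

test_that("panel assignment enforces disjoint non-empty sides", {
  expect_error(panel_assignment(character(), "d"), "at least one")
  expect_error(panel_assignment("a", character()), "at least one")
  expect_error(panel_assignment(c("a", "b"), c("b", "c")), "disjoint")
  p <- panel_assignment(c("b", "a"), "c")
  expect_identical(p$up, c("a", "b"))  # canonical order
})

test_that("direction assignment splits validated markers and rejects degenerate sets", {
  res <- rbind(differential_row("m150", 0.7, 0.001, "mann_whitney"),
               differential_row("m497", -1.3, 0.001, "mann_whitney"),
               differential_row("m369", -1.7, 0.01, "mann_whitney"),
               differential_row("m301", -0.9, 0.01, "mann_whitney"),
               differential_row("m1976", -0.6, 0.03, "mann_whitney"),
               differential_row("m610", -1.8, 0.03, "mann_whitney"))
  dirs <- assign_directions(res)
  expect_identical(dirs$up, "m150")
  expect_length(dirs$down, 5)
  all_up <- rbind(differential_row("a", 1, 0.01, "t"),
                  differential_row("b", 2, 0.01, "t"))
  expect_error(assign_directions(all_up), "down-regulated")
  expect_error(assign_directions(differential_row("a", 0, 0.5, "t")), "flat")
  minimal <- rbind(differential_row("a", 1, .01, "t"),
                   differential_row("b", -1, .01, "t"))
  expect_identical(assign_directions(minimal), list(up = "a", down = "b"))
})

test_that("panel enumeration counts match (2^N - 1)(2^M - 1)", {
  expect_length(enumerate_panels("u1", paste0("d", 1:5)), 31)
  expect_length(enumerate_panels("u1", "d1"), 1)
  expect_length(enumerate_panels(c("u1", "u2"), paste0("d", 1:3)), 21)
  set.seed(31)
  for (rep in 1:5) {
    nu <- sample(1:3, 1); nd <- sample(1:4, 1)
    panels <- enumerate_panels(paste0("u", 1:nu), paste0("d", 1:nd))
    expect_length(panels, (2^nu - 1) * (2^nd - 1))
    expect_length(unique(vapply(panels, function(p)
      paste(c(p$up, "/", p$down), collapse = ","), character(1))),
      length(panels))
  }
  expect_error(enumerate_panels(paste0("u", 1:7), paste0("d", 1:7),
                                max_panels = 100), "backward_search")
})

test_that("panel evaluation separates planted groups and handles nulls", {
  d <- planted_qpcr_design(c(u = 2, d = -2), sigma = 0.3, n_benign = 50,
                           n_early = 50, seed = 33)
  co <- gen_qpcr_cohort(d)
  expr <- linearize(normalize_delta_ct(co$expr))
  ev <- evaluate_panel(expr, co$meta, panel_assignment("u", "d"))
  expect_gte(ev$roc$auc, 0.95)
  null_d <- planted_qpcr_design(c(u = 0, d = 0), sigma = 1, n_benign = 200,
                                n_early = 200, seed = 34)
  co0 <- gen_qpcr_cohort(null_d)
  ev0 <- evaluate_panel(linearize(normalize_delta_ct(co0$expr)), co0$meta,
                        panel_assignment("u", "d"))
  expect_equal(ev0$roc$auc, 0.5, tolerance = 0.1)
  # samples with missing members are skipped and recorded
  v <- unclass(normalize_delta_ct(co$expr)); v["u", 1] <- NA
  ev_na <- evaluate_panel(linearize(expr_matrix(v, scale = "delta_ct")),
                          co$meta, panel_assignment("u", "d"))
  expect_identical(ev_na$skipped, colnames(co$expr)[1])
  expect_false(colnames(co$expr)[1] %in% names(ev_na$udr_scores))
})

test_that("backward search respects side constraints and the tie rule", {
  # 1 up + 1 down: no legal removal, path of length 1
  d <- planted_qpcr_design(c(u = 1, d = -1), sigma = 0.5, n_benign = 20,
                           n_early = 20, seed = 35)
  co <- gen_qpcr_cohort(d)
  expr <- linearize(normalize_delta_ct(co$expr))
  path <- backward_search(expr, co$meta, "u", "d")
  expect_length(path, 1)
  # exact AUC tie between removing d1 and d2 (identical rows): lexicographic
  d2 <- planted_qpcr_design(c(u = 1.5, noise1 = 0, d9 = -1.5), sigma = 0.6,
                            n_benign = 40, n_early = 40, seed = 36)
  co2 <- gen_qpcr_cohort(d2)
  v <- unclass(normalize_delta_ct(co2$expr))
  v <- rbind(v, noise2 = v["noise1", ])  # duplicate noise row
  expr2 <- linearize(expr_matrix(v, scale = "delta_ct"))
  path2 <- backward_search(expr2, co2$meta, "u", c("d9", "noise1", "noise2"))
  if (length(path2) > 1) {
    removed <- setdiff(c(path2[[1]]$panel$down), path2[[2]]$panel$down)
    expect_identical(removed, "noise1")  # tie broken by smallest id
  }
  expect_gte(length(path2), 1)
})

test_that("exhaustive search dominates backward search on random instances", {
  set.seed(37)
  for (rep in 1:8) {
    nu <- sample(1:3, 1); nd <- sample(1:(7 - nu - 1), 1) + 1
    nd <- min(nd, 7 - nu)
    effects <- c(stats::setNames(runif(nu, 0, 1.5), paste0("u", seq_len(nu))),
                 stats::setNames(-runif(nd, 0, 1.5), paste0("d", seq_len(nd))))
    d <- planted_qpcr_design(effects, sigma = 1, n_benign = 15, n_early = 15,
                             seed = 400 + rep)
    co <- gen_qpcr_cohort(d)
    expr <- linearize(normalize_delta_ct(co$expr))
    ups <- paste0("u", seq_len(nu)); dns <- paste0("d", seq_len(nd))
    evs <- lapply(enumerate_panels(ups, dns), function(p)
      evaluate_panel(expr, co$meta, p, ci = FALSE))
    best <- max(vapply(evs, function(e) e$roc$auc, numeric(1)))
    fin <- backward_search(expr, co$meta, ups, dns)
    expect_gte(best + 1e-12, fin[[length(fin)]]$roc$auc)
  }
})

test_that("log-UDR matches the closed-form binormal AUC", {
  # independent log2-normal members, unit variance, planted shifts
  up_d <- c(up1 = 0.8, up2 = 1.2)
  dn_d <- c(dn1 = -0.5, dn2 = -1.0)
  delta <- mean(up_d) + mean(abs(dn_d))
  v <- 1 / 2 + 1 / 2                       # 1/N + 1/M per group
  target <- stats::pnorm(delta / sqrt(2 * v))
  d <- planted_qpcr_design(c(up_d, dn_d), sigma = 1, n_benign = 10000,
                           n_early = 10000, seed = 38)
  co <- gen_qpcr_cohort(d)
  expr <- linearize(normalize_delta_ct(co$expr))
  ev <- evaluate_panel(expr, co$meta, panel_assignment(names(up_d), names(dn_d)),
                       type = "log")
  expect_equal(ev$roc$auc, target, tolerance = 0.01 / target)
})

test_that("parsimony selection ranks by size, AUC, then member order", {
  fake <- function(up, down, auc) structure(
    list(panel = panel_assignment(up, down), udr_scores = numeric(),
         roc = structure(list(auc = auc), class = "roc_result"),
         cohort_tag = "x"), class = "panel_evaluation")
  six <- fake("u", paste0("d", 1:5), 0.897)
  four <- fake("u", paste0("d", 1:3), 0.952)
  three <- fake("u", paste0("d", 1:2), 0.940)
  sel <- select_optimal(list(six, four, three), parsimony_epsilon = 0.02)
  expect_length(sel, 2)
  expect_identical(sel[[1]]$panel, three$panel)   # smaller panel first
  expect_identical(sel[[2]]$panel, four$panel)
  argmax <- select_optimal(list(six, four, three), parsimony_epsilon = 0)
  expect_length(argmax, 1)
  expect_identical(argmax[[1]]$panel, four$panel)
  expect_identical(select_optimal(list(six), 0.02)[[1]]$panel, six$panel)
  expect_error(select_optimal(list(), 0.02), "no panel")
})
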