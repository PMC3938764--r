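# Hand-built significance grids for criterion-level unit tests.
fake_grid <- function(p, sign = "+", L = 10) {
  dn <- list(p_x = seq_len(L), p_y = seq_len(L))
  structure(list(y = "Y", x = "X", L_max = L,
                 p = matrix(p, L, L, dimnames = dn),
                 bin = matrix(cellwiring:::.bin_p(matrix(p, L, L)), L, L,
                              dimnames = dn),
                 sign = matrix(sign, L, L, dimnames = dn),
                 adj_r2 = matrix(0.2, L, L, dimnames = dn),
                 n = matrix(1000, L, L, dimnames = dn),
                 autocorrelation = c(1, rep(0.4, L)), spearman = 0.3,
                 sign_method = "spearman", form = "f"),
            class = "sig_grid")
}

test_that("edge criterion behaves on dominant, empty and mixed grids", {
  # fully significant, sign-consistent grid: edge declared
  e1 <- infer_edge(fake_grid(1e-6, "-"))
  expect_true(e1$declared)
  expect_equal(e1$sign, "-")
  expect_true(all(e1$checks))
  # all-ns grid: no edge
  e2 <- infer_edge(fake_grid(0.5))
  expect_false(e2$declared)
  # strong but sign-inconsistent grid fails criterion (c)
  g3 <- fake_grid(1e-6)
  g3$sign[1:5, ] <- "-"
  e3 <- infer_edge(g3)
  expect_false(e3$declared)
  expect_false(e3$checks["c"])
  # thresholds are configurable
  e4 <- infer_edge(g3, edge_criterion(require_sign_consistency = FALSE))
  expect_true(e4$declared)
  # borderline: 60% at 0.05 but too few at 0.0001 fails criterion (b)
  g5 <- fake_grid(0.5)
  g5$p[, 1:6] <- 0.01
  e5 <- infer_edge(g5)
  expect_true(e5$checks["a"])
  expect_false(e5$checks["b"])
  expect_false(e5$declared)
})

test_that("reciprocal analysis classifies injected directions", {
  # unidirectional X -> Y
  sim <- simulate_var_panel(coupled_var_spec(-0.5), 80, 50, seed = 3)
  ra <- reciprocal_analysis(sim$panel, x = "F1", y = "F2", L_max = 5)
  expect_equal(ra$classification, "X->Y")
  expect_equal(ra$edge_xy$sign, "-")
  # bidirectional when both couplings are injected
  sp2 <- var_spec(2, coupling = array(c(0.4, 0.45, -0.45, 0.4), c(1, 2, 2)))
  sim2 <- simulate_var_panel(sp2, 80, 50, seed = 4)
  ra2 <- reciprocal_analysis(sim2$panel, x = "F1", y = "F2", L_max = 5)
  expect_equal(ra2$classification, "bidirectional")
  # independent features: none
  sim0 <- simulate_var_panel(null_var_spec(), 60, 40, seed = 5)
  ra0 <- reciprocal_analysis(sim0$panel, x = "F1", y = "F2", L_max = 5)
  expect_equal(ra0$classification, "none")
})

test_that("causal graphs collect declared edges and verify chains", {
  # 3-feature chain A -> B (-) -> C (+) in a VAR
  cp <- array(0, c(1, 3, 3))
  diag(cp[1, , ]) <- 0.45
  cp[1, 2, 1] <- -0.5     # A -> B negative
  cp[1, 3, 2] <- 0.5      # B -> C positive
  sp <- var_spec(3, coupling = cp, feature_names = c("A", "B", "C"))
  sim <- simulate_var_panel(sp, 80, 50, seed = 6)
  g <- causal_graph(sim$panel, c("A", "B", "C"), L_max = 5)
  ch <- assemble_chain(g, c("A", "B", "C"))
  expect_true(ch$intact)
  expect_equal(ch$links$sign, c("-", "+"))
  # chain over an absent edge reports the broken position
  ch2 <- assemble_chain(g, c("C", "A"))
  expect_false(ch2$intact)
  expect_equal(ch2$broken_at, 1L)
  # single-edge chain equals the edge decision
  ch3 <- assemble_chain(g, c("A", "B"))
  expect_equal(ch3$intact,
               any(g$edges$source == "A" & g$edges$target == "B"))
})

test_that("plasticity comparison labels conserved/lost/gained/inverted", {
  mk_graph <- function(edges, cond) structure(
    list(edges = edges, tests = list(), features = c("A", "B", "C"),
         condition = cond, criterion = edge_criterion()),
    class = "causal_graph")
  e1 <- data.frame(source = c("A", "B", "A"), target = c("B", "C", "C"),
                   sign = c("+", "-", "+"), frac_sig = 1, frac_strong = 1)
  e2 <- data.frame(source = c("A", "C"), target = c("B", "B"),
                   sign = c("-", "+"), frac_sig = 1, frac_strong = 1)
  rep <- compare_conditions(list(ctrl = mk_graph(e1, "ctrl"),
                                 rho = mk_graph(e2, "rho")))
  tab <- rep$table
  status_of <- function(s, t)
    tab$status[tab$source == s & tab$target == t]
  expect_equal(status_of("A", "B"), "sign-inverted")
  expect_equal(status_of("B", "C"), "lost")
  expect_equal(status_of("A", "C"), "lost")
  expect_equal(status_of("C", "B"), "gained")
  # identical graphs: everything conserved
  rep2 <- compare_conditions(list(a = mk_graph(e1, "a"),
                                  b = mk_graph(e1, "b")))
  expect_true(all(rep2$table$status == "conserved"))
})
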