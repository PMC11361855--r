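# Network blocks: embeddings, focused attention, convolutions, fusion,
# losses and the analytic gradients.

test_that("config invariants are enforced", {
  expect_error(pepperm_config(d_model = 10, heads = 4),
               class = "pepperm_input_error")
  expect_error(pepperm_config(lambda_g = 1.5), class = "pepperm_input_error")
  expect_error(pepperm_config(kernel = 4), class = "pepperm_input_error")
  expect_error(pepperm_config(channels = c(8, 16)),
               class = "pepperm_input_error")
})

test_that("atom embedding follows the scaled two-term formula", {
  W_node <- matrix(0.5, 30, 4)
  W_bond <- matrix(-0.25, 6, 4)
  node <- matrix(seq(0, 1, length.out = 30), 1, 30)
  bond <- matrix(c(0, 1, 1.5, 0, 0, 2), 1, 6)
  x <- atom_embed(node, bond, W_node, W_bond)
  # hand computation: (sum(node)*0.5 + sum(bond)*(-0.25)) / sqrt(4)
  expect_equal(x[1, 1], (sum(node) * 0.5 + sum(bond) * -0.25) / 2)
  expect_equal(ncol(x), 4)

  # linearity: all-zero inputs give zero; zero node weights isolate bond
  expect_true(all(atom_embed(node * 0, bond * 0, W_node, W_bond) == 0))
  x_bond_only <- atom_embed(node, bond, W_node * 0, W_bond)
  node2 <- matrix(runif(30), 1, 30)
  expect_equal(x_bond_only, atom_embed(node2, bond, W_node * 0, W_bond))
})

test_that("focused attention behaves at the strength extremes", {
  cf <- tiny_config()
  params <- init_pepperm_params(cf, seed = 3)
  set.seed(11)
  n <- 5
  x <- matrix(rnorm(n * cf$d_model), n, cf$d_model)

  # attention probability rows form a simplex before strength masking
  ones <- matrix(1, n, n)
  out <- focused_block(x, ones, params, cf, return_attention = TRUE)
  for (P in out$attention[[1]]) {
    expect_equal(rowSums(P), rep(1, n))
    expect_true(all(P >= 0))
  }

  # identity strength: only the atom's own value row contributes.
  # Scaling another atom's value projection input cannot leak in through
  # the value path: compare against a manual masked-attention computation.
  ident <- diag(n)
  out_id <- focused_block(x, ident, params, cf, return_attention = TRUE)
  lp <- pepperm:::layer_params(params, "graph", 1)
  V <- x %*% lp$Wv + rep(lp$bv, each = n)
  dh <- cf$d_model / cf$heads
  manual <- matrix(0, n, cf$d_model)
  for (h in seq_len(cf$heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    P <- out_id$attention[[1]][[h]]
    manual[, cols] <- diag(diag(P)) %*% V[, cols]   # only self-values survive
  }
  focus_manual <- manual %*% lp$Wo + rep(lp$bo, each = n)
  ln1 <- pepperm:::layer_norm_fwd(x + focus_manual, lp$ln1g, lp$ln1b)
  pre <- ln1$y %*% lp$W1 + rep(lp$b1, each = n)
  f <- pmax(pre, 0) %*% lp$W2 + rep(lp$b2, each = n)
  ln2 <- pepperm:::layer_norm_fwd(ln1$y + f, lp$ln2g, lp$ln2b)
  expect_equal(out_id$x, ln2$y, tolerance = 1e-12)
})

test_that("cyclic convolution is rotation-invariant at full length", {
  cf <- tiny_config(conv_kind = "cyclic")
  params <- init_pepperm_params(cf, seed = 5)
  L <- cf$max_len
  set.seed(2)
  m <- matrix(rnorm(L * 16), L, 16)
  base <- monomer_forward(m, c(0, L), params, cf)
  for (r in 1:(L - 1)) {
    rot <- m[((seq_len(L) - 1 + r) %% L) + 1, ]
    out <- monomer_forward(rot, c(0, L), params, cf)
    expect_equal(out$out, base$out, tolerance = 1e-9)
    expect_equal(out$layer_feat, base$layer_feat, tolerance = 1e-9)
  }

  # plain and cyclic convolution differ on the same input
  cfp <- tiny_config(conv_kind = "plain")
  expect_gt(max(abs(monomer_forward(m, c(0, L), params, cfp)$out - base$out)),
            1e-6)
})

test_that("monomer branch is invariant to frame padding beyond the span", {
  L <- 4
  set.seed(6)
  rows <- matrix(rnorm(L * 16), L, 16)
  for (kind in c("plain", "cyclic")) {
    cf_small <- tiny_config(max_len = 6, conv_kind = kind)
    cf_big <- tiny_config(max_len = 12, conv_kind = kind)
    params <- init_pepperm_params(cf_small, seed = 8)  # same weights fit both
    m_small <- rbind(rows, matrix(0, 2, 16))
    m_big <- rbind(rows, matrix(0, 8, 16))
    o1 <- monomer_forward(m_small, c(0, L), params, cf_small)
    o2 <- monomer_forward(m_big, c(0, L), params, cf_big)
    expect_equal(o1$out, o2$out, tolerance = 1e-9, label = kind)
  }
})

test_that("zero monomer input with zero biases gives a zero latent", {
  cf <- tiny_config()
  params <- init_pepperm_params(cf, seed = 4)
  out <- monomer_forward(matrix(0, cf$max_len, 16), c(0, 3), params, cf)
  expect_equal(unname(out$out), rep(0, cf$latent))
})

test_that("peptide branch separates descriptor and fingerprint paths", {
  cf <- tiny_config()
  params <- init_pepperm_params(cf, seed = 6)
  desc <- rnorm(16)
  fp <- as.numeric(runif(2048) < 0.05)

  # hand computation of the two-branch merge
  relu <- function(v) pmax(v, 0)
  x_desc <- drop(relu(desc %*% params$pep.D1 + params$pep.bd1) %*% params$pep.D2) + params$pep.bd2
  x_fp <- drop(relu(fp %*% params$pep.F1 + params$pep.bf1) %*% params$pep.F2) + params$pep.bf2
  manual <- drop(c(x_desc, x_fp) %*% params$pep.W_out) + params$pep.b_out
  got <- peptide_forward(desc, fp, params, cf)
  expect_equal(got$out, manual, tolerance = 1e-12)
  expect_equal(got$layer_feat, (x_desc + x_fp) / 2, tolerance = 1e-12)

  # freeze the descriptor branch at zero: flipping a fingerprint bit moves
  # the output, perturbing descriptors does not
  pz <- params
  pz$pep.D1[] <- 0; pz$pep.D2[] <- 0; pz$pep.bd1[] <- 0; pz$pep.bd2[] <- 0
  base <- peptide_forward(desc, fp, pz, cf)$out
  expect_equal(peptide_forward(rnorm(16), fp, pz, cf)$out, base)
  fp2 <- fp; fp2[which(fp == 0)[1]] <- 1
  expect_gt(max(abs(peptide_forward(desc, fp2, pz, cf)$out - base)), 0)

  # all-zero weights give a zero output
  p0 <- params
  for (nm in grep("^pep\\.", names(p0), value = TRUE)) p0[[nm]][] <- 0
  expect_equal(unname(peptide_forward(desc, fp, p0, cf)$out), rep(0, cf$latent))
})

test_that("fusion head concatenates, routes and stays deterministic", {
  cf <- tiny_config()
  params <- init_pepperm_params(cf, seed = 9)
  lat <- list(atom = rnorm(cf$latent), monomer = rnorm(cf$latent),
              peptide = abs(rnorm(cf$latent)))

  expect_error(fusion_forward(list(atom = lat$atom, monomer = lat$monomer),
                              params, cf),
               class = "pepperm_input_error")
  expect_identical(fusion_forward(lat, params, cf),
                   fusion_forward(lat, params, cf))

  # zero latents through a zero-bias shared layer give zero
  p0 <- params
  p0$fus.bs1[] <- 0; p0$fus.bs2 <- 0
  z <- list(atom = rep(0, cf$latent), monomer = rep(0, cf$latent),
            peptide = rep(0, cf$latent))
  expect_equal(fusion_forward(z, p0, cf), 0)

  # wire the shared layer to copy the peptide latent's first coordinate
  pr <- params
  pr$fus.S1[] <- 0
  pr$fus.S1[2 * cf$latent + 1, 1] <- 1       # first peptide coordinate
  pr$fus.bs1[] <- 0
  pr$fus.S2[] <- 0; pr$fus.S2[1, 1] <- 1; pr$fus.bs2 <- 0
  expect_equal(fusion_forward(lat, pr, cf), lat$peptide[1])
})

test_that("the seven-component loss combines with the stated weights", {
  ones <- list(fusion = 1, atom = 1, monomer = 1, peptide = 1,
               layer_a = 1, layer_m = 1, layer_p = 1)
  lb <- total_loss(ones, gamma_sub = 0.10, gamma_layer = 0.05)
  expect_equal(lb$total, 1.45)
  expect_equal(total_loss(ones, 0, 0)$total, 1)

  # exact predictions mean zero loss everywhere
  preds <- c(fusion = -6, atom = -6, monomer = -6, peptide = -6,
             layer_a = -6, layer_m = -6, layer_p = -6)
  zl <- total_loss(pepperm:::sample_losses(preds, -6))
  expect_equal(zl$total, 0)

  # total >= fusion for nonnegative components and weights
  set.seed(10)
  for (i in 1:20) {
    ls <- as.list(stats::setNames(runif(7), names(ones)))
    lb <- total_loss(ls, runif(1), runif(1))
    expect_gte(lb$total, lb$fusion)
  }

  expect_error(total_loss(list(fusion = 1)), class = "pepperm_input_error")
})

test_that("analytic gradients match central finite differences", {
  cf <- tiny_config()
  params <- init_pepperm_params(cf, seed = 7)
  sm <- toy_sample(cf)
  loss_fn <- function(p) {
    fw <- pepperm:::forward_sample(sm, p, cf)
    total_loss(pepperm:::sample_losses(fw$preds, sm$label),
               cf$gamma_sub, cf$gamma_layer)$total
  }
  fw <- pepperm:::forward_sample(sm, params, cf)
  acc <- pepperm:::acc_new()
  pepperm:::backward_sample(fw, sm, sm$label, params, cf, acc)

  eps <- 1e-5
  set.seed(12)
  for (nm in names(params)) {
    g <- acc[[nm]]
    expect_false(is.null(g), label = sprintf("gradient present for %s", nm))
    i <- sample(length(params[[nm]]), 1)
    p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
    num <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
    expect_equal(as.numeric(g)[i], num, tolerance = 1e-4,
                 label = sprintf("grad %s[%d]", nm, i))
  }
})

test_that("auxiliary losses give every branch a nonzero gradient", {
  cf <- tiny_config()
  params <- init_pepperm_params(cf, seed = 13)
  sm <- toy_sample(cf, seed = 77)
  fw <- pepperm:::forward_sample(sm, params, cf)
  acc <- pepperm:::acc_new()
  pepperm:::backward_sample(fw, sm, sm$label, params, cf, acc)
  for (nm in c("atom.W_node", "atom.graph.l1.Wq", "atom.conf.l1.Wq",
               "mono.l1.W", "mono.l2.W", "pep.D1", "pep.F1", "fus.S1")) {
    expect_gt(max(abs(acc[[nm]])), 0, label = nm)
  }
})

test_that("atom forward on a padded feature set equals the trimmed sample", {
  cf <- tiny_config()
  params <- init_pepperm_params(cf, seed = 15)
  smi <- "CC(=O)NCC(=O)O"
  cs <- generate_conformers(smi, 1, 6)
  afs <- atom_feature_set(smi, cs$coordinates[[1]], n_max = cf$n_max)
  padded <- atom_forward(afs, params, cf)
  n <- afs$n_real
  trimmed <- atom_forward(list(
    node = afs$node[1:n, ], bond = afs$bond[1:n, ],
    sg = afs$strength_graph[1:n, 1:n], sc = afs$strength_conf[1:n, 1:n]),
    params, cf)
  expect_equal(padded$out, trimmed$out, tolerance = 1e-12)
  expect_equal(padded$layer_feat, trimmed$layer_feat, tolerance = 1e-12)

  # lambda_g at the extremes makes one block irrelevant
  cf1 <- tiny_config(lambda_g = 1)
  sc_perturbed <- afs
  sc_perturbed$strength_conf <- afs$strength_conf * 0.5
  diag(sc_perturbed$strength_conf) <- 1
  sc_perturbed$strength_conf[!afs$mask, ] <- 0
  sc_perturbed$strength_conf[, !afs$mask] <- 0
  expect_equal(atom_forward(afs, params, cf1)$out,
               atom_forward(sc_perturbed, params, cf1)$out, tolerance = 1e-12)
})
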