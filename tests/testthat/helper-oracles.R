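# Independent oracles and small shared fixtures.

# Runge-Kutta oracle for the two-compartment kinetics, integrated segment
# by segment so the piecewise-constant rates stay smooth within each call.
ode_kinetics_oracle <- function(g, times) {
  in_pulse <- function(t) t >= g$pulse_start && t < g$pulse_end
  brk <- c(g$pulse_start, g$pulse_end)
  brk <- brk[is.finite(brk) & brk > 0]
  grid <- sort(unique(c(0, brk, times)))
  y <- c(u = g$alpha_baseline / g$beta, s = g$alpha_baseline / g$gamma)
  out <- matrix(NA_real_, length(grid), 2)
  out[1, ] <- y
  for (i in seq_len(length(grid) - 1)) {
    a <- if (in_pulse(grid[i])) g$alpha_baseline * g$alpha_pulse
         else g$alpha_baseline
    gam <- if (in_pulse(grid[i])) g$gamma * g$gamma_pulse else g$gamma
    f <- function(t, y, p) list(c(a - g$beta * y[1],
                                  g$beta * y[1] - gam * y[2]))
    o <- deSolve::ode(y, c(grid[i], grid[i + 1]), f, NULL, method = "ode45",
                      rtol = 1e-12, atol = 1e-14)
    y <- o[nrow(o), c("u", "s")]
    out[i + 1, ] <- y
  }
  data.frame(time = times, u = out[match(times, grid), 1],
             s = out[match(times, grid), 2])
}

# brute-force per-read re-evaluation of the counting schemes (independent
# of the vectorized implementation; plain per-read loop over pre-extracted
# columns)
brute_force_counts <- function(reads, frac_overlap = 0.9, non_overlap = 3) {
  genes <- sort(unique(reads$gene_id))
  res <- matrix(0L, length(genes), 3, dimnames = list(genes, c("i", "ii", "iii")))
  gid <- reads$gene_id
  spl <- reads$split
  exo <- reads$exon_overlap_fraction
  tro <- reads$transcript_overlap_fraction
  unm <- reads$unmatched_bases
  pri <- reads$primary
  str <- reads$strand_match
  groups <- split(seq_len(nrow(reads)), reads$read_id)
  for (ix in groups) {
    for (scheme in c("i", "ii", "iii")) {
      fr <- if (scheme == "iii") tro[ix] else exo[ix]
      ok <- pri[ix] & str[ix] & unm[ix] <= non_overlap & fr >= frac_overlap
      if (scheme != "i") ok <- ok & !spl[ix]
      if (!any(ok)) next
      fa <- fr[ok]
      ga <- gid[ix][ok]
      top <- which(fa == max(fa))
      if (length(top) > 1) next
      g <- ga[top]
      col <- match(scheme, c("i", "ii", "iii"))
      res[g, col] <- res[g, col] + 1L
    }
  }
  data.frame(gene_id = genes, exonic_all = res[, "i"],
             exonic_nonsplit = res[, "ii"],
             transcript_nonsplit = res[, "iii"], row.names = NULL)
}

# adjusted Rand index between two partitions (closed-form from the
# contingency table)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ind <- sum_a * sum_b / choose(n, 2)
  max_ind <- (sum_a + sum_b) / 2
  if (max_ind == exp_ind) return(1)
  (sum_ij - exp_ind) / (max_ind - exp_ind)
}

# simple logFC estimate from count matrices: log2 ratio of group means
count_logfc <- function(counts, samples, t1, t0 = 0) {
  m1 <- rowMeans(counts[, samples$timepoint == t1, drop = FALSE])
  m0 <- rowMeans(counts[, samples$timepoint == t0, drop = FALSE])
  log2(m1 / m0)
}

# one decay-mechanism simulation: transcriptional shutdown vs doubled decay
# rate on the same half-life panel, counts at a single timepoint
decay_mechanism_sim <- function(seed, mechanism, t = 4, n_genes = 250,
                                n_replicates = 4, library_size = 2e6,
                                nb_dispersion = 0.02) {
  set.seed(seed)
  hl <- exp(rnorm(n_genes, log(4.5), 0.8))
  panel <- lapply(seq_along(hl), function(i) {
    if (mechanism == "shutdown") {
      gene_kinetics(sprintf("g%03d", i), alpha_baseline = 10,
                    alpha_pulse = 0, pulse_start = 0, pulse_end = Inf,
                    half_life = hl[i])
    } else {
      gene_kinetics(sprintf("g%03d", i), alpha_baseline = 10,
                    alpha_pulse = 1, gamma_pulse = 2, pulse_start = 0,
                    pulse_end = Inf, half_life = hl[i])
    }
  })
  d <- course_design(timepoints = t, regions = "dHC",
                     n_replicates = n_replicates,
                     library_size = library_size,
                     nb_dispersion = nb_dispersion, seed = seed)
  sim <- simulate_bulk_counts(d, panel)
  fc <- count_logfc(sim$processed, sim$samples, t)
  hl_tab <- data.frame(gene_id = names(fc), t_half = hl)
  decay_consistency(names(fc), fc, hl_tab, t = t)
}

# planted-TF simulation: expression with a step effect at 45 min on the
# targets of the active TFs; returns everything differential_activity needs
sim_tf_study <- function(seed, n_tf = 200, n_active = 10, n_targets = 10,
                         n_genes = 2000, effect = 1, noise_sd = 0.3,
                         n_rep = 3, timepoints = c(0, 0.75, 1.5)) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  reg <- data.frame(
    tf = rep(sprintf("TF%03d", seq_len(n_tf)), each = n_targets),
    target = sample(genes, n_tf * n_targets, replace = FALSE),
    category = sample(c("A", "B", "C", "D"), n_tf * n_targets, replace = TRUE),
    mode = sample(c(1, -1), n_tf * n_targets, replace = TRUE, prob = c(.8, .2)))
  regs <- suppressMessages(build_regulons(reg))
  design <- expand.grid(replicate = seq_len(n_rep), timepoint = timepoints,
                        region = c("dHC", "vHC"), stringsAsFactors = FALSE)
  expr <- matrix(rnorm(n_genes * nrow(design), 5, noise_sd), n_genes,
                 dimnames = list(genes, NULL))
  active <- sprintf("TF%03d", seq_len(n_active))
  hit <- design$timepoint == 0.75
  for (tf in active) {
    sub <- regs[regs$tf == tf, ]
    expr[sub$target, hit] <- expr[sub$target, hit] + effect * sub$mode
  }
  tf_logcpm <- setNames(rep(5, n_tf), sprintf("TF%03d", seq_len(n_tf)))
  list(expr = expr, regulons = regs, design = design, active = active,
       tf_logcpm = tf_logcpm)
}

# planted-origin cell-type simulation wrapper
sim_celltype_study <- function(seed, n_genes = 60, amp = 1) {
  cts <- data.frame(
    celltype = c("neurons", "astrocytes", "vascular", "oligodendrocytes",
                 "microglia"),
    abundance = c(0.45, 0.2, 0.1, 0.15, 0.1))
  set.seed(seed)
  origin <- sample(cts$celltype, n_genes, replace = TRUE)
  genes <- lapply(seq_len(n_genes), function(i) {
    gene_kinetics(sprintf("g%03d", i), alpha_baseline = 20,
                  alpha_pulse = sample(c(6, 0.25), 1), pulse_start = 0,
                  pulse_end = 0.75, half_life = 2,
                  celltype_amplitude = setNames(amp, origin[i]))
  })
  list(celltypes = cts, genes = genes, origin = origin)
}
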