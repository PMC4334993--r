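# Shared fixtures (lazily built, cached for the test run) and independent
# oracle implementations. Oracles deliberately avoid the package's own
# computation paths: direct triple loops, standalone Kabsch, brute-force
# greedy clustering, Monte-Carlo sphere integration.

.cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.cache[[key]])) .cache[[key]] <- build()
  .cache[[key]]
}

toy_channel_neg <- function() cached("tc_neg", function() make_toy_channel())
toy_channel_pos <- function() cached("tc_pos", function()
  make_toy_channel(toy_channel_params(pocket = "positive")))
toy_peptide1 <- function() cached("pep1", function() make_toy_peptide())

# dock runs shared between acceptance gates (deterministic, config-tagged)
cached_dock <- function(key, receptor, ligand, config) {
  cached(paste0("dock_", key), function() dock_rigid(receptor, ligand, config))
}

fast_cfg <- function(...) dock_config(rotation_step = 90, top_n = 50, ...)

# --- random score grids for the FFT-vs-direct gate -------------------------
random_grids <- function(seed, dims = c(10, 10, 10), spacing = 1.2) {
  set.seed(seed)
  g <- list(origin = c(0, 0, 0), spacing = spacing, dims = dims,
            surface = array(rbinom(prod(dims), 1, 0.2), dims),
            core = array(rbinom(prod(dims), 1, 0.1), dims),
            charge = array(rnorm(prod(dims), 0, 0.3) *
                             rbinom(prod(dims), 1, 0.15), dims))
  class(g) <- "score_grids"
  g
}

# direct periodic cross-correlation C(d) = sum_v R(v) L(v - d)
direct_corr3 <- function(R, L) {
  dims <- dim(R)
  out <- array(0, dims)
  for (dx in 0:(dims[1] - 1)) for (dy in 0:(dims[2] - 1))
    for (dz in 0:(dims[3] - 1)) {
      Ls <- L[((0:(dims[1] - 1) - dx) %% dims[1]) + 1,
              ((0:(dims[2] - 1) - dy) %% dims[2]) + 1,
              ((0:(dims[3] - 1) - dz) %% dims[3]) + 1]
      out[dx + 1, dy + 1, dz + 1] <- sum(R * Ls)
    }
  out
}

# direct periodic convolution phi(v) = sum_u q(u) k(v - u)
direct_conv3 <- function(Q, K) {
  dims <- dim(Q)
  out <- array(0, dims)
  nz <- which(Q != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    u <- nz[r, ]
    Ks <- K[((0:(dims[1] - 1) - u[1] + 1) %% dims[1]) + 1,
            ((0:(dims[2] - 1) - u[2] + 1) %% dims[2]) + 1,
            ((0:(dims[3] - 1) - u[3] + 1) %% dims[3]) + 1]
    out <- out + Q[u[1], u[2], u[3]] * Ks
  }
  out
}

# full direct score maps matching the documented scan definition
direct_scan_oracle <- function(rec, lig, core_penalty = 9, r_cut = 10) {
  kern <- vestidock:::coulomb_kernel(rec$dims, rec$spacing, r_cut)
  phi <- direct_conv3(rec$charge, kern)
  list(shape = direct_corr3(rec$surface, lig$surface) -
         core_penalty * direct_corr3(rec$core, lig$core),
       elec = -direct_corr3(phi, lig$charge))
}

# --- standalone Kabsch (independent of vestidock::superpose) ---------------
oracle_kabsch <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  sv <- svd(t(A) %*% B)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rmsd <- sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  list(rotation = R, rmsd = rmsd)
}

# --- brute-force greedy clustering oracle ----------------------------------
oracle_greedy <- function(rmsd_matrix, radius) {
  n <- nrow(rmsd_matrix)
  unassigned <- rep(TRUE, n)
  clusters <- list()
  while (any(unassigned)) {
    best <- -1L; best_count <- -1L
    for (i in seq_len(n)) {
      if (!unassigned[i]) next
      cnt <- 0L
      for (j in seq_len(n))
        if (unassigned[j] && rmsd_matrix[i, j] <= radius) cnt <- cnt + 1L
      if (cnt > best_count) { best_count <- cnt; best <- i }
    }
    members <- integer(0)
    for (j in seq_len(n))
      if (unassigned[j] && rmsd_matrix[best, j] <= radius)
        members <- c(members, j)
    unassigned[members] <- FALSE
    clusters[[length(clusters) + 1L]] <-
      list(center = best, members = members, size = length(members))
  }
  clusters
}

# synthetic pose_list over random rigid placements of a tiny ligand
synth_poses <- function(n, seed, spread = 20) {
  set.seed(seed)
  rots <- rotation_set(90)
  df <- data.frame(
    rank = seq_len(n),
    score = sort(runif(n, 0, 100), decreasing = TRUE),
    shape = 0, elec = 0, contact = 0,
    rotation_index = sample(length(rots), n, replace = TRUE),
    tx = runif(n, -spread, spread), ty = runif(n, -spread, spread),
    tz = runif(n, -spread, spread))
  structure(list(poses = df, rotations = rots,
                 ligand_centroid = c(0, 0, 0),
                 receptor_id = "synth", ligand_id = "synth",
                 config = dock_config()),
            class = "pose_list")
}

# RMSD matrix computed independently (explicit per-pair transform + formula;
# the documented convention rotates about the ligand centroid)
oracle_rmsd_matrix <- function(poses, ca) {
  n <- nrow(poses$poses)
  ctr <- colMeans(ca)
  place <- function(i) {
    p <- poses$poses[i, ]
    R <- poses$rotations[[p$rotation_index]]
    sweep(sweep(ca, 2, ctr) %*% t(R), 2, ctr + c(p$tx, p$ty, p$tz), `+`)
  }
  placed <- lapply(seq_len(n), place)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- sqrt(mean(rowSums((placed[[i]] - placed[[j]])^2)))
  m
}

# --- Monte-Carlo two-sphere SASA oracle ------------------------------------
oracle_two_sphere_mc <- function(r1, r2, d, n_mc = 1e6, seed = 42) {
  set.seed(seed)
  area_one <- function(rs, center, other_c, other_r) {
    u <- matrix(rnorm(3 * n_mc), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * rs, 2, center, `+`)
    free <- rowSums(sweep(p, 2, other_c)^2) >= other_r^2
    mean(free) * 4 * pi * rs^2
  }
  area_one(r1, c(0, 0, 0), c(d, 0, 0), r2) +
    area_one(r2, c(d, 0, 0), c(0, 0, 0), r1)
}

# minimal atom-table constructor for hand-built fixtures
atoms_df <- function(name, resname, resseq, xyz, chain = "A",
                     element = substr(name, 1, 1)) {
  data.frame(serial = seq_along(name), name = name, altloc = "",
             resname = resname, chain = chain, resseq = as.integer(resseq),
             icode = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
             element = element, stringsAsFactors = FALSE)
}

# all-atom structure for an arbitrary sequence on an ideal backbone
seq_structure <- function(seq1, phi = -57, psi = -47, chain = "A") {
  aa <- strsplit(seq1, "")[[1]]
  bb <- vestidock:::build_backbone(rep(phi, length(aa)), rep(psi, length(aa)))
  rows <- lapply(seq_along(aa), function(i) {
    rt <- vestidock:::AA_1TO3[[aa[i]]]
    bbn <- c("N", "CA", "C", "O")
    bbc <- t(vapply(bbn, function(nm) bb[[i]][[nm]], double(3)))
    block <- atoms_df(bbn, rt, i, bbc, chain = chain)
    if (rt != "GLY") {
      sc <- vestidock:::build_sidechain(rt, bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C,
                                        chi = c(-60, 180, 180, 180))
      block <- rbind(block, atoms_df(sc$name, rt, i,
                                     as.matrix(sc[, c("x", "y", "z")]),
                                     chain = chain))
    }
    block
  })
  out <- do.call(rbind, rows)
  out$serial <- seq_len(nrow(out))
  out
}

TPN_SEQ <- "ALCNCNRIIIPHMCWKKCGKK"

# compare atom tables ignoring serials and row names
expect_same_atoms <- function(a, b, cols = c("name", "altloc", "resname",
                                             "chain", "resseq", "icode",
                                             "x", "y", "z", "element")) {
  a <- a[, cols]; b <- b[, cols]
  rownames(a) <- NULL; rownames(b) <- NULL
  expect_identical(a, b)
}

exact_rz <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
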