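# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the code paths they check.

# --- minimum-volume enclosing ellipsoid: independent oracle ---------------
# D-optimal-design dual (maximize log det over the probability simplex)
# solved by SciPy's SLSQP with explicit bound/equality constraints and an
# analytic gradient, run to tight tolerance, then converted to the primal
# ellipsoid volume. Shares no code with the package's coordinate-ascent
# implementation. Batched: one subprocess solves many point sets.
mvee_oracle_volumes <- function(point_sets) {
  stopifnot(is.list(point_sets))
  df <- dplyr::bind_rows(lapply(seq_along(point_sets), function(i) {
    p <- as.matrix(point_sets[[i]])
    data.frame(set = i, x = p[, 1], y = p[, 2], z = p[, 3])
  }))
  data_csv <- tempfile(fileext = ".csv")
  out_csv <- tempfile(fileext = ".csv")
  utils::write.csv(df, data_csv, row.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, csv",
    "import numpy as np",
    "from scipy.optimize import minimize",
    "def vol(pts):",
    "    P = pts.T; d, n = P.shape",
    "    Q = np.vstack([P, np.ones(n)])",
    "    def negld(u):",
    "        X = Q @ (u[:, None] * Q.T)",
    "        return -np.linalg.slogdet(X)[1]",
    "    def jac(u):",
    "        X = Q @ (u[:, None] * Q.T)",
    "        return -np.einsum('ij,ij->j', Q, np.linalg.solve(X, Q))",
    "    cons = [{'type': 'eq', 'fun': lambda u: u.sum() - 1.0,",
    "             'jac': lambda u: np.ones(n)}]",
    "    res = minimize(negld, np.full(n, 1.0 / n), jac=jac,",
    "                   bounds=[(0.0, 1.0)] * n, constraints=cons,",
    "                   method='SLSQP', options={'maxiter': 1000, 'ftol': 1e-14})",
    "    u = np.clip(res.x, 0, None); u /= u.sum()",
    "    c = P @ u",
    "    S = P @ (u[:, None] * P.T) - np.outer(c, c)",
    "    A = np.linalg.inv(S) / d",
    "    ev = np.linalg.eigvalsh((A + A.T) / 2)",
    "    return 4 / 3 * np.pi * np.prod(1 / np.sqrt(ev))",
    "rows = list(csv.DictReader(open(sys.argv[1])))",
    "sets = {}",
    "for r in rows:",
    "    sets.setdefault(int(r['set']), []).append(",
    "        [float(r['x']), float(r['y']), float(r['z'])])",
    "with open(sys.argv[2], 'w') as fh:",
    "    fh.write('set,volume\\n')",
    "    for k in sorted(sets):",
    "        fh.write('%d,%.15g\\n' % (k, vol(np.array(sets[k]))))"
  ), script)
  status <- system2("python", c(script, data_csv, out_csv))
  stopifnot(status == 0)
  res <- utils::read.csv(out_csv)
  res$volume[order(res$set)]
}

mvee_oracle_volume <- function(points) {
  mvee_oracle_volumes(list(points))[1]
}

# --- optimal-superposition RMSD: quaternion (Horn) method ------------------
rmsd_oracle_quaternion <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  Sxx <- crossprod(A0, B0)
  K <- matrix(0, 4, 4)
  K[1, 1] <- Sxx[1, 1] + Sxx[2, 2] + Sxx[3, 3]
  K[1, 2] <- K[2, 1] <- Sxx[2, 3] - Sxx[3, 2]
  K[1, 3] <- K[3, 1] <- Sxx[3, 1] - Sxx[1, 3]
  K[1, 4] <- K[4, 1] <- Sxx[1, 2] - Sxx[2, 1]
  K[2, 2] <- Sxx[1, 1] - Sxx[2, 2] - Sxx[3, 3]
  K[2, 3] <- K[3, 2] <- Sxx[1, 2] + Sxx[2, 1]
  K[2, 4] <- K[4, 2] <- Sxx[1, 3] + Sxx[3, 1]
  K[3, 3] <- -Sxx[1, 1] + Sxx[2, 2] - Sxx[3, 3]
  K[3, 4] <- K[4, 3] <- Sxx[2, 3] + Sxx[3, 2]
  K[4, 4] <- -Sxx[1, 1] - Sxx[2, 2] + Sxx[3, 3]
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max((sum(A0^2) + sum(B0^2) - 2 * lambda) / nrow(A), 0))
}

# --- random rigid motions --------------------------------------------------
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

apply_rigid <- function(xyz, rotation = random_rotation(),
                        translation = rnorm(3, sd = 5)) {
  xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
}

# --- simple fixtures -------------------------------------------------------
simple_topology <- function(n, element = "C", residue_id = 1L, chain = "A") {
  topology(tibble::tibble(
    atom_name = paste0(element, seq_len(n)), element = element,
    residue_name = "RES", residue_id = residue_id, chain_id = chain))
}

# templates whose pairwise optimal-superposition RMSD all exceed min_rmsd
make_separated_templates <- function(k, n_atoms, min_rmsd, seed) {
  set.seed(seed)
  repeat {
    tpl <- lapply(seq_len(k), function(i) matrix(rnorm(3 * n_atoms, sd = 10), n_atoms))
    ok <- TRUE
    if (k > 1) {
      for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        if (rmsd_oracle_quaternion(tpl[[a]], tpl[[b]]) <= min_rmsd) ok <- FALSE
      }
    }
    if (ok) return(tpl)
  }
}

# write a small multi-model PDB file from raw text blocks
write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}
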