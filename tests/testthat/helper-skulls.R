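# shared fixtures: all built in code at test time

scheme33 <- cranial_scheme()

random_proper_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply an independent random rigid motion + scaling to every specimen
apply_rigid_motions <- function(df, seed, scale_range = c(0.5, 3)) {
  set.seed(seed)
  for (id in unique(df$specimen_id)) {
    i <- df$specimen_id == id
    m <- as.matrix(df[i, c("x", "y", "z")])
    m <- m %*% random_proper_rotation() * runif(1, scale_range[1], scale_range[2])
    m <- sweep(m, 2, runif(3, -20, 20), `+`)
    df[i, c("x", "y", "z")] <- m
  }
  df
}

# delete whole landmarks (set coordinates NA) for one specimen table
delete_landmarks <- function(df, landmarks, specimen = NULL) {
  i <- df$landmark %in% landmarks
  if (!is.null(specimen)) i <- i & df$specimen_id %in% specimen
  df$x[i] <- NA_real_
  df$y[i] <- NA_real_
  df$z[i] <- NA_real_
  df
}

# one-specimen long tibble from a coordinate matrix
tbl_from_matrix <- function(m, id = "s1", taxon = id) {
  tibble::tibble(specimen_id = id, taxon = taxon, landmark = seq_len(nrow(m)),
                 x = m[, 1], y = m[, 2], z = m[, 3])
}

# planted-direction tangent vector helpers (internal functions under test
# support; accessed via :::)
planted_vector <- function(magnitude, seed) {
  tpl <- template_skull(scheme33, 1)
  basis <- craniomorph:::similarity_basis(tpl)
  set.seed(seed)
  craniomorph:::plant_vector(tpl, magnitude, basis)
}

# rotate a template-frame 3k vector into the aligned (canonical) frame of a fit
to_aligned_frame <- function(v, fit) {
  tpl <- template_skull(fit$scheme, 1)
  r <- craniomorph:::kabsch_rotation(tpl, fit$consensus)
  as.vector(t(craniomorph:::unflatten_config(v) %*% r))
}
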