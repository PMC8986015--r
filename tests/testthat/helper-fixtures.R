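# small fixtures built in code, shared across test files

# 5-point template with a single curve: anchors 1 and 5, semis 2-4
curve5_template <- function() {
  landmark_template("curve5", 5,
                    curves = list(list(id = "c", semis = 2:4,
                                       anchors = c(1L, 5L))))
}

# gently curved 5-point space curve (mm scale)
curve5_reference <- function() {
  t <- seq(0, 1, length.out = 5)
  cbind(10 * t, 3 * sin(pi * t), 1.5 * t^2)
}

# random landmark set around a reference with iid noise
random_set <- function(n, reference, template, sd = 0.05, seed = 1) {
  set.seed(seed)
  k <- nrow(reference)
  arr <- array(NA_real_, c(k, 3, n))
  for (i in seq_len(n)) arr[, , i] <- reference + matrix(rnorm(k * 3, 0, sd), k, 3)
  landmark_set(arr, template)
}

# arbitrary proper rotation from three angles
rotation_xyz <- function(a, b, c) {
  rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rx %*% ry %*% rz
}

# apply a similarity transform (rotation, scale, translation) to one config
similarity_transform <- function(cfg, rot = diag(3), scale = 1, shift = c(0, 0, 0)) {
  sweep(scale * cfg %*% rot, 2, shift, `+`)
}

# a plain template without curves/semilandmarks
plain_template <- function(k, name = "plain") landmark_template(name, k)
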