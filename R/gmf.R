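# Vertex layout convention used throughout: a face is a numeric vector of
# length V*3 with coordinates interleaved per vertex (x1, y1, z1, x2, ...).
# Per-vertex scalar fields (e.g. diagnostic weights) have length V and are
# broadcast to all three coordinates of a vertex with rep(w, each = 3).

#' Build the demographic design matrix
#'
#' Expands a table of demographic factors (binary sex, continuous age,
#' categorical ethnicity) into a fixed-order design matrix containing a
#' constant, all main effects, and all two- and three-way interactions.
#' Ethnicity is coded with treatment dummies against its first level, so a
#' three-level ethnicity factor contributes two dummy columns and the full
#' factor set yields 12 columns. Age is centered before interaction columns
#' are formed to reduce collinearity; the centering value is stored in the
#' returned spec so new rows can be coded consistently.
#'
#' Column order is fixed: constant, sex, age, ethnicity dummies, sex:age,
#' sex:ethnicity, age:ethnicity, sex:age:ethnicity.
#'
#' @param factors data.frame with any subset of columns `sex` (0/1 or a
#'   two-level factor), `age` (numeric years), `ethnicity` (factor or
#'   character). An empty selection yields the constant column only.
#' @param spec optional coding spec from a previous call (or a fitted model);
#'   guarantees identical column layout for new data and makes unknown
#'   ethnicity levels an error.
#' @return object of class `design_matrix`: list with `values` (N x M
#'   matrix), `column_names`, and `spec` (ethnicity levels, age center).
#' @export
build_design_matrix <- function(factors, spec = NULL) {
  if (is.null(factors)) factors <- data.frame(row.names = 1L)
  stopifnot(is.data.frame(factors))
  n <- nrow(factors)
  if (n < 1L) stop("need at least one row of factor values")

  have_sex <- "sex" %in% names(factors)
  have_age <- "age" %in% names(factors)
  have_eth <- "ethnicity" %in% names(factors)

  if (is.null(spec)) {
    eth_levels <- if (have_eth) {
      e <- factors$ethnicity
      if (is.factor(e)) levels(e) else sort(unique(as.character(e)))
    } else character(0)
    age_center <- if (have_age) mean(as.numeric(factors$age)) else 0
    spec <- list(ethnicity_levels = eth_levels, age_center = age_center,
                 have = c(sex = have_sex, age = have_age, ethnicity = have_eth))
  } else {
    have_sex <- spec$have[["sex"]]; have_age <- spec$have[["age"]]
    have_eth <- spec$have[["ethnicity"]]
  }

  cols <- list("(const)" = rep(1, n))

  sex <- NULL
  if (have_sex) {
    s <- factors$sex
    if (is.factor(s) || is.character(s)) s <- as.integer(factor(s)) - 1L
    sex <- as.numeric(s)
    if (!all(sex %in% c(0, 1))) stop("sex must be binary (0/1 or two levels)")
    cols[["sex"]] <- sex
  }
  age <- NULL
  if (have_age) {
    age <- as.numeric(factors$age) - spec$age_center
    cols[["age"]] <- age
  }
  eth <- NULL
  if (have_eth) {
    e <- as.character(factors$ethnicity)
    unknown <- setdiff(unique(e), spec$ethnicity_levels)
    if (length(unknown) > 0L)
      stop("unknown ethnicity level(s): ", paste(unknown, collapse = ", "))
    ref <- spec$ethnicity_levels[1L]
    dummy_levels <- spec$ethnicity_levels[-1L]
    eth <- lapply(dummy_levels, function(l) as.numeric(e == l))
    names(eth) <- paste0("eth_", dummy_levels)
    for (nm in names(eth)) cols[[nm]] <- eth[[nm]]
  }
  # interactions, in documented order
  if (have_sex && have_age) cols[["sex:age"]] <- sex * age
  if (have_sex && have_eth)
    for (nm in names(eth)) cols[[paste0("sex:", nm)]] <- sex * eth[[nm]]
  if (have_age && have_eth)
    for (nm in names(eth)) cols[[paste0("age:", nm)]] <- age * eth[[nm]]
  if (have_sex && have_age && have_eth)
    for (nm in names(eth)) cols[[paste0("sex:age:", nm)]] <- sex * age * eth[[nm]]

  values <- do.call(cbind, cols)
  colnames(values) <- names(cols)
  vars <- apply(values[, -1L, drop = FALSE], 2L, stats::var)
  if (n > 1L && any(vars == 0))
    warning("constant design column(s) kept: ",
            paste(colnames(values)[-1L][vars == 0], collapse = ", "))
  structure(list(values = values, column_names = colnames(values), spec = spec),
            class = "design_matrix")
}

#' Fit the demographic factor model
#'
#' Least-squares fit of the demographic design matrix to each vertex
#' coordinate (and optionally each texture value): data = X A + E.
#'
#' @param db a `face_db` (see [generate_face_database()]) or a list with
#'   `shape` (N x V*3 matrix) and `factors`.
#' @param design optional pre-built `design_matrix`.
#' @return list with `A` (M x V*3 coefficients), `E` (N x V*3 residuals),
#'   `design`; plus `A_texture`/`E_texture` when texture is present.
#' @export
fit_factor_model <- function(db, design = NULL) {
  if (is.null(design)) design <- build_design_matrix(db$factors)
  X <- design$values
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank-deficient (rank ", qrX$rank, " < ", ncol(X),
         " columns); remove redundant factors or interactions")
  fit_block <- function(Y) {
    A <- qr.coef(qrX, Y)
    E <- Y - X %*% A
    list(A = A, E = E)
  }
  sb <- fit_block(db$shape)
  out <- list(A = sb$A, E = sb$E, design = design)
  if (!is.null(db$texture)) {
    tb <- fit_block(db$texture)
    out$A_texture <- tb$A
    out$E_texture <- tb$E
  }
  out
}

#' Orthogonal residual basis
#'
#' Economy singular value decomposition of the residual matrix E = U S V',
#' giving an orthonormal basis for individual identity variation after
#' demographic effects are removed.
#'
#' @param E N x D residual matrix.
#' @param K number of components to keep; `NULL` keeps `min(N, D)`. Requests
#'   beyond the numerical rank are truncated with a warning.
#' @return list with `U` (D x K, orthonormal columns), `d` (K singular
#'   values, non-increasing), `V` (N x K).
#' @export
residual_basis <- function(E, K = NULL) {
  E <- as.matrix(E)
  kmax <- min(dim(E))
  if (is.null(K)) K <- kmax
  if (K > kmax) stop("K exceeds min(dim(E)) = ", kmax)
  sv <- svd(E)
  tol <- max(dim(E)) * .Machine$double.eps * max(sv$d, 0)
  rk <- sum(sv$d > tol)
  if (K > rk && rk > 0L) {
    warning("K = ", K, " exceeds numerical rank ", rk, "; truncating")
    K <- rk
  }
  if (rk == 0L) K <- min(K, 1L)  # degenerate all-zero residuals
  # SVD convention here puts exemplars on V and coordinates on U
  list(U = sv$v[, seq_len(K), drop = FALSE],
       d = sv$d[seq_len(K)],
       V = sv$u[, seq_len(K), drop = FALSE])
}

#' Fit a generative model of faces
#'
#' Two-stage fit: a demographic general linear model absorbs sex, age,
#' ethnicity and their interactions; the residuals are orthogonally
#' decomposed into an identity basis. Identity coordinates ("components")
#' are stored unit-variance: raw basis coordinates are divided by
#' d/sqrt(N-1), and synthesis multiplies the scale back, so component
#' magnitudes are comparable across basis directions.
#'
#' @param db a `face_db`.
#' @param K number of shape components to retain (default: full rank).
#' @param K_texture number of texture components (when texture present).
#' @return object of class `gmf_model`.
#' @export
gmf_fit <- function(db, K = NULL, K_texture = NULL) {
  fm <- fit_factor_model(db)
  n <- nrow(db$shape)
  rb <- residual_basis(fm$E, K)
  model <- list(
    A_shape = fm$A,
    U_shape = rb$U,
    s_shape = rb$d,
    V_shape = rb$V,
    scale_shape = rb$d / sqrt(n - 1),
    K_shape = length(rb$d),
    n_exemplars = n,
    n_vertices = ncol(db$shape) / 3L,
    design_spec = fm$design$design_spec %||% fm$design$spec
  )
  if (!is.null(db$texture)) {
    rbt <- residual_basis(fm$E_texture, K_texture)
    model$A_texture <- fm$A_texture
    model$U_texture <- rbt$U
    model$s_texture <- rbt$d
    model$V_texture <- rbt$V
    model$scale_texture <- rbt$d / sqrt(n - 1)
    model$K_texture <- length(rbt$d)
  }
  structure(model, class = "gmf_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gmf_model <- function(x, ...) {
  cat("Generative model of faces\n")
  cat("  exemplars:", x$n_exemplars, "  vertices:", x$n_vertices, "\n")
  cat("  shape components:", x$K_shape, "\n")
  if (!is.null(x$K_texture)) cat("  texture components:", x$K_texture, "\n")
  invisible(x)
}

design_row <- function(factors, model) {
  build_design_matrix(factors, spec = model$design_spec)$values
}

#' Categorical-average ("prototype") face for given factor values
#'
#' @param factors one-row data.frame of factor values.
#' @param model fitted `gmf_model`.
#' @param what `"shape"` or `"texture"`.
#' @return numeric vector (length V*3 for shape).
#' @export
gmf_prototype <- function(factors, model, what = "shape") {
  X <- design_row(factors, model)
  A <- if (what == "shape") model$A_shape else model$A_texture
  drop(X %*% A)
}

#' Synthesize a face from identity components
#'
#' vertices = prototype(factors) + U (components * scale), where scale
#' restores the stored unit-variance component convention.
#'
#' @param components length-K numeric vector of identity coordinates.
#' @param factors one-row data.frame of demographic values.
#' @param model fitted `gmf_model`.
#' @param what `"shape"` or `"texture"`.
#' @return flat numeric vector of vertex coordinates (or texture values).
#' @export
synthesize_vertices <- function(components, factors, model, what = "shape") {
  U <- if (what == "shape") model$U_shape else model$U_texture
  sc <- if (what == "shape") model$scale_shape else model$scale_texture
  K <- ncol(U)
  if (length(components) != K)
    stop("components has length ", length(components), ", expected ", K)
  gmf_prototype(factors, model, what) + drop(U %*% (components * sc))
}

#' Project a face into identity-component coordinates
#'
#' Least-squares coordinates of (vertices - prototype) in the orthonormal
#' residual basis (the pseudoinverse of U is its transpose), rescaled to the
#' unit-variance component convention. Inverse of [synthesize_vertices()] on
#' the basis range.
#'
#' @inheritParams synthesize_vertices
#' @param vertices flat numeric vector, length V*3.
#' @return length-K numeric vector of components.
#' @export
project_components <- function(vertices, factors, model, what = "shape") {
  U <- if (what == "shape") model$U_shape else model$U_texture
  sc <- if (what == "shape") model$scale_shape else model$scale_texture
  if (length(vertices) != nrow(U))
    stop("vertices has length ", length(vertices), ", expected ", nrow(U))
  resid <- vertices - gmf_prototype(factors, model, what)
  drop(crossprod(U, resid)) / sc
}

#' Construct an amplified face
#'
#' Per-vertex convex (or extrapolated) mixture of a ground-truth face and the
#' categorical average: F = G * (C a) + prototype * (1 - C a), applied to all
#' three coordinates of each vertex. With a = 0 the prototype is returned;
#' with C = 1, a = 1 the ground truth.
#'
#' @param ground_truth flat V*3 vector (target identity).
#' @param prototype flat V*3 vector (categorical average).
#' @param C per-vertex weight in `[0, 1]`, length V (or already length V*3).
#' @param alpha non-negative amplification level. Values of `C * alpha`
#'   beyond 1 extrapolate past the ground truth and are reported via a
#'   message.
#' @return flat V*3 numeric vector.
#' @export
construct_amplified_face <- function(ground_truth, prototype, C, alpha) {
  stopifnot(length(ground_truth) == length(prototype), alpha >= 0)
  if (any(C < 0) || any(C > 1)) stop("C must lie in [0, 1]")
  if (length(C) * 3L == length(ground_truth)) C <- rep(C, each = 3L)
  if (length(C) != length(ground_truth))
    stop("C must have length V or V*3")
  ca <- C * alpha
  if (any(ca > 1)) message("C * alpha exceeds 1 for ", sum(ca > 1),
                           " coordinates (extrapolating past ground truth)")
  ground_truth * ca + prototype * (1 - ca)
}

#' Outward vertex normals of a prototype face
#'
#' Synthetic vertex clouds in this package are sphere-like; outward normals
#' are taken as unit vectors from the cloud centroid to each vertex. Used to
#' project per-vertex displacements onto a single inward-outward axis.
#'
#' @param prototype flat V*3 vector.
#' @return V x 3 matrix of unit normals.
#' @export
vertex_normals <- function(prototype) {
  Vm <- matrix(prototype, ncol = 3L, byrow = TRUE)
  ctr <- colMeans(Vm)
  D <- sweep(Vm, 2L, ctr)
  nrm <- sqrt(rowSums(D^2))
  nrm[nrm == 0] <- 1
  D / nrm
}
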