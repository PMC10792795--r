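## Internal vectorized implementation of the separable-convolution refiner.
##
## Activations live in (B*H*W) x C matrices; within one image the spatial
## index runs column-major (y fastest), i.e. row p = (b-1)*H*W + y + (x-1)*H.
## 3x3 depthwise convolutions are computed as nine shifted gathers with a
## shared zero "pad" row appended to the activation matrix; 1x1 pointwise
## convolutions are plain matrix products, so BLAS carries the bulk of the
## arithmetic. Gradients use the adjoint relations: the input gradient of a
## depthwise convolution is the same convolution with the kernel flipped.

# Precomputed gather indices for one (H, W, batch B) geometry.
.convGeometry <- function(H, W, B) {
    HW <- H * W
    N <- B * HW
    pad <- N + 1L
    ys <- rep(seq_len(H), times = W)
    xs <- rep(seq_len(W), each = H)
    offs <- expand.grid(dy = -1:1, dx = -1:1)  # k runs dy-fastest; flip: 10-k
    batchOff <- rep((seq_len(B) - 1L) * HW, each = HW)
    idx <- vector("list", 9L)
    for (k in 1:9) {
        y2 <- ys + offs$dy[k]
        x2 <- xs + offs$dx[k]
        p1 <- y2 + (x2 - 1L) * H
        p1[y2 < 1L | y2 > H | x2 < 1L | x2 > W] <- NA_integer_
        full <- rep(p1, times = B) + batchOff
        full[is.na(full)] <- pad
        idx[[k]] <- as.integer(full)
    }
    # 2x2 max-pool / stride-2 subsampling targets
    H2 <- H %/% 2L; W2 <- W %/% 2L
    y2 <- rep(seq_len(H2), times = W2)
    x2 <- rep(seq_len(W2), each = H2)
    batchOff2 <- rep((seq_len(B) - 1L) * HW, each = H2 * W2)
    cell <- function(dy, dx)
        as.integer(rep((2L * y2 - 1L + dy) + (2L * x2 - 2L + dx) * H,
                       times = B) + batchOff2)
    list(H = H, W = W, B = B, N = N, pad = pad, idx = idx,
         pool = list(cell(0L, 0L), cell(1L, 0L), cell(0L, 1L), cell(1L, 1L)),
         sub = cell(0L, 0L))
}

.dwForward <- function(A, W9, geom) {
    Ap <- rbind(A, 0)
    out <- Ap[geom$idx[[1L]], , drop = FALSE] *
        rep(W9[1L, ], each = geom$N)
    for (k in 2:9)
        out <- out + Ap[geom$idx[[k]], , drop = FALSE] *
            rep(W9[k, ], each = geom$N)
    out
}

# Input gradient of .dwForward: convolution with the flipped kernel.
.dwBackwardInput <- function(G, W9, geom) {
    Gp <- rbind(G, 0)
    out <- Gp[geom$idx[[9L]], , drop = FALSE] * rep(W9[1L, ], each = geom$N)
    for (k in 2:9)
        out <- out + Gp[geom$idx[[10L - k]], , drop = FALSE] *
            rep(W9[k, ], each = geom$N)
    out
}

# Kernel gradient: dW9[k, c] = sum_p A[p + o_k, c] * G[p, c].
.dwBackwardKernel <- function(A, G, geom) {
    Ap <- rbind(A, 0)
    t(vapply(1:9, function(k)
        colSums(Ap[geom$idx[[k]], , drop = FALSE] * G),
        numeric(ncol(A))))
}

.maxPoolForward <- function(A, geom) {
    C <- ncol(A)
    m <- A[geom$pool[[1L]], , drop = FALSE]
    src <- matrix(geom$pool[[1L]], nrow(m), C)
    for (k in 2:4) {
        cand <- A[geom$pool[[k]], , drop = FALSE]
        w <- cand > m
        m[w] <- cand[w]
        src[w] <- matrix(geom$pool[[k]], nrow(m), C)[w]
    }
    list(out = m, src = src)
}

.maxPoolBackward <- function(G, src, geom) {
    C <- ncol(G)
    nOut <- nrow(G)
    dA <- matrix(0, geom$N, C)
    lin <- as.vector(src) + rep((seq_len(C) - 1L) * geom$N, each = nOut)
    dA[lin] <- as.vector(G)  # pooling windows are disjoint: plain assignment
    dA
}

# He-style initialization of all parameter tensors (consumes RNG stream).
.initParams <- function(cfg) {
    cIn <- 7L
    params <- list()
    for (b in seq_len(cfg@nBlocks)) {
        f <- cfg@filters[b]
        params[[paste0("dw1_", b)]] <- matrix(
            stats::rnorm(9L * cIn, 0, sqrt(2 / 9)), 9L, cIn)
        params[[paste0("pw1_", b)]] <- matrix(
            stats::rnorm(cIn * f, 0, sqrt(2 / cIn)), cIn, f)
        params[[paste0("b1_", b)]] <- numeric(f)
        params[[paste0("dw2_", b)]] <- matrix(
            stats::rnorm(9L * f, 0, sqrt(2 / 9)), 9L, f)
        params[[paste0("pw2_", b)]] <- matrix(
            stats::rnorm(f * f, 0, sqrt(2 / f)), f, f)
        params[[paste0("b2_", b)]] <- numeric(f)
        params[[paste0("sc_", b)]] <- matrix(
            stats::rnorm(cIn * f, 0, sqrt(2 / cIn)), cIn, f)
        params[[paste0("bsc_", b)]] <- numeric(f)
        cIn <- f
    }
    fL <- cfg@filters[cfg@nBlocks]
    nFeat <- 3L * fL + 21L  # final-map moments plus 7 input-channel moments
    params$Wd <- matrix(stats::rnorm(nFeat * 12L, 0, sqrt(1 / nFeat)),
                        nFeat, 12L)
    params$bd <- rep(0.5, 12L)  # outputs live in [0, 1]; start mid-range
    params
}

# Per-sample, per-channel global moments of a non-negative activation map:
# mean mass plus mass-normalized spatial centroids (soft-argmax style), so a
# feature map concentrated at a location reports that location at O(1) scale.
.momentPool <- function(P, grp, gx, gy, hw, eps = 1e-3) {
    S <- rowsum(P, grp, reorder = FALSE)
    m <- S / hw
    xc <- rowsum(P * gx, grp, reorder = FALSE) / (S + eps)
    yc <- rowsum(P * gy, grp, reorder = FALSE) / (S + eps)
    list(m = m, xc = xc, yc = yc, S = S)
}

.momentGrid <- function(H, W, B) {
    list(grp = rep(seq_len(B), each = H * W),
         gx = rep(rep((seq_len(W) - 0.5) / W, each = H), times = B),
         gy = rep(rep((seq_len(H) - 0.5) / H, times = W), times = B),
         hw = H * W)
}

# Geometries for every block depth at batch size B (cached by the caller).
.refinerGeoms <- function(cfg, B) {
    lapply(seq_len(cfg@nBlocks), function(b)
        .convGeometry(cfg@inputHeight %/% (2L^(b - 1L)),
                      cfg@inputWidth %/% (2L^(b - 1L)), B))
}

# Forward pass. X: (B*H*W) x 7. Returns predictions plus (optionally) the
# cache needed for the backward pass. Dropout (inverted) is active only when
# training = TRUE and consumes the RNG stream. `bn` carries the running
# feature-normalization statistics (batch statistics are used when training).
.refinerForward <- function(params, X, geoms, cfg, B, training = FALSE,
                            keepCache = training,
                            bn = list(mean = 0, var = 1)) {
    A <- X
    drop <- cfg@dropoutRate
    cache <- if (keepCache) vector("list", cfg@nBlocks) else NULL
    for (b in seq_len(cfg@nBlocks)) {
        g <- geoms[[b]]
        Z1 <- .dwForward(A, params[[paste0("dw1_", b)]], g)
        H1 <- Z1 %*% params[[paste0("pw1_", b)]]
        H1 <- H1 + rep(params[[paste0("b1_", b)]], each = nrow(H1))
        A1 <- H1 * (H1 > 0)
        Z2 <- .dwForward(A1, params[[paste0("dw2_", b)]], g)
        H2 <- Z2 %*% params[[paste0("pw2_", b)]]
        H2 <- H2 + rep(params[[paste0("b2_", b)]], each = nrow(H2))
        mp <- .maxPoolForward(H2, g)
        S <- A[g$sub, , drop = FALSE] %*% params[[paste0("sc_", b)]]
        S <- S + rep(params[[paste0("bsc_", b)]], each = nrow(S))
        R <- mp$out + S
        O <- R * (R > 0)
        dm <- NULL
        if (training && drop > 0) {
            dm <- matrix(stats::rbinom(length(O), 1L, 1 - drop) / (1 - drop),
                         nrow(O), ncol(O))
            O <- O * dm
        }
        if (keepCache)
            cache[[b]] <- list(A = A, Z1 = Z1, H1 = H1, A1 = A1, Z2 = Z2,
                               src = mp$src, R = R, dropMask = dm)
        A <- O
    }
    # global moment pooling on the final feature maps (mean mass plus
    # mass-normalized centroids), concatenated with the same moments of the
    # 7 input channels — an input-level residual that lets the prior encoded
    # in the heatmap channels reach the linear head untouched by pooling
    gL <- geoms[[cfg@nBlocks]]
    mg <- .momentGrid(gL$H %/% 2L, gL$W %/% 2L, B)
    P <- A  # block outputs are already non-negative
    mom <- .momentPool(P, mg$grp, mg$gx, mg$gy, mg$hw)
    mg0 <- .momentGrid(cfg@inputHeight, cfg@inputWidth, B)
    P0 <- X * (X > 0)
    mom0 <- .momentPool(P0, mg0$grp, mg0$gx, mg0$gy, mg0$hw)
    feat <- cbind(mom$m, mom$xc, mom$yc, mom0$m, mom0$xc, mom0$yc)
    # batch normalization of the pooled features: the moment features have
    # widely different scales, and normalizing them is what makes the head
    # trainable within a few epochs; inference uses running statistics
    if (training) {
        mu <- colMeans(feat)
        v <- colMeans(feat^2) - mu^2
        bnNew <- if (is.null(bn$seen))
            list(mean = mu, var = v, seen = TRUE)
        else
            list(mean = 0.9 * bn$mean + 0.1 * mu,
                 var = 0.9 * bn$var + 0.1 * v, seen = TRUE)
    } else {
        mu <- bn$mean
        v <- bn$var
        bnNew <- bn
    }
    sdv <- sqrt(v + 1e-5)
    zRaw <- (feat - rep(mu, each = B)) / rep(sdv, each = B)
    z <- zRaw
    featDrop <- NULL
    if (training && drop > 0) {
        featDrop <- matrix(stats::rbinom(length(z), 1L, 1 - drop) / (1 - drop),
                           nrow(z), ncol(z))
        z <- z * featDrop
    }
    pred <- z %*% params$Wd + rep(params$bd, each = B)
    if (keepCache)
        list(pred = pred, z = z, zRaw = zRaw, featDrop = featDrop,
             bnSd = sdv, bn = bnNew, finalA = A, mom = mom, mg = mg,
             cache = cache)
    else list(pred = pred, bn = bnNew)
}

# Backward pass from dPred; returns the gradient list (same names as params).
.refinerBackward <- function(params, fwd, geoms, cfg, B, dPred) {
    grads <- list()
    grads$Wd <- t(fwd$z) %*% dPred
    grads$bd <- colSums(dPred)
    dZ <- dPred %*% t(params$Wd)
    if (!is.null(fwd$featDrop)) dZ <- dZ * fwd$featDrop
    # batch-normalization backward, per feature column
    zR <- fwd$zRaw
    dFeat <- (dZ - rep(colMeans(dZ), each = B) -
              zR * rep(colMeans(dZ * zR), each = B)) /
        rep(fwd$bnSd, each = B)
    fL <- cfg@filters[cfg@nBlocks]
    # input-channel moment features (last 21 columns) carry no gradient
    dm <- dFeat[, seq_len(fL), drop = FALSE]
    dxc <- dFeat[, fL + seq_len(fL), drop = FALSE]
    dyc <- dFeat[, 2L * fL + seq_len(fL), drop = FALSE]
    mg <- fwd$mg
    mom <- fwd$mom
    grp <- mg$grp
    Sg <- mom$S[grp, , drop = FALSE] + 1e-3
    dA <- dm[grp, , drop = FALSE] / mg$hw +
        (dxc[grp, , drop = FALSE] * (mg$gx - mom$xc[grp, , drop = FALSE]) +
         dyc[grp, , drop = FALSE] * (mg$gy - mom$yc[grp, , drop = FALSE])) / Sg
    for (b in rev(seq_len(cfg@nBlocks))) {
        g <- geoms[[b]]
        cc <- fwd$cache[[b]]
        if (!is.null(cc$dropMask)) dA <- dA * cc$dropMask
        dR <- dA * (cc$R > 0)
        # shortcut branch
        Asub <- cc$A[g$sub, , drop = FALSE]
        grads[[paste0("sc_", b)]] <- t(Asub) %*% dR
        grads[[paste0("bsc_", b)]] <- colSums(dR)
        dAsc <- matrix(0, g$N, ncol(cc$A))
        dAsc[g$sub, ] <- dR %*% t(params[[paste0("sc_", b)]])
        # main branch
        dH2 <- .maxPoolBackward(dR, cc$src, g)
        grads[[paste0("pw2_", b)]] <- t(cc$Z2) %*% dH2
        grads[[paste0("b2_", b)]] <- colSums(dH2)
        dZ2 <- dH2 %*% t(params[[paste0("pw2_", b)]])
        grads[[paste0("dw2_", b)]] <- .dwBackwardKernel(cc$A1, dZ2, g)
        dA1 <- .dwBackwardInput(dZ2, params[[paste0("dw2_", b)]], g)
        dH1 <- dA1 * (cc$H1 > 0)
        grads[[paste0("pw1_", b)]] <- t(cc$Z1) %*% dH1
        grads[[paste0("b1_", b)]] <- colSums(dH1)
        dZ1 <- dH1 %*% t(params[[paste0("pw1_", b)]])
        grads[[paste0("dw1_", b)]] <- .dwBackwardKernel(cc$A, dZ1, g)
        dA <- .dwBackwardInput(dZ1, params[[paste0("dw1_", b)]], g) + dAsc
    }
    grads
}

.adamInit <- function(params)
    list(m = lapply(params, function(p) p * 0),
         v = lapply(params, function(p) p * 0), t = 0L)

.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    state$t <- state$t + 1L
    c1 <- 1 - beta1^state$t
    c2 <- 1 - beta2^state$t
    for (nm in names(params)) {
        g <- grads[[nm]]
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
        params[[nm]] <- params[[nm]] -
            lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    }
    list(params = params, state = state)
}

# Masked mean-squared-error loss and its gradient.
.maskedMSE <- function(pred, truth, mask) {
    nm <- sum(mask)
    if (nm == 0) return(list(loss = 0, grad = pred * 0, n = 0))
    diff <- (pred - truth) * mask
    list(loss = sum(diff^2) / nm, grad = 2 * diff / nm, n = nm)
}
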