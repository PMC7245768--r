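# Independent oracles used across the test files. These are deliberate
# re-derivations straight from the defining formulas, kept free of any
# package internals, so they can disagree with the implementation.

# Plain-R CIEDE2000 (kL = kC = kH = 1), a direct transcription of the
# published formula with hue arithmetic in degrees.
oracle_ciede2000 <- function(lab1, lab2) {
    L1 <- lab1[1]; a1 <- lab1[2]; b1 <- lab1[3]
    L2 <- lab2[1]; a2 <- lab2[2]; b2 <- lab2[3]
    deg <- function(r) r * 180 / pi
    rad <- function(d) d * pi / 180
    C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
    Cbar <- (C1 + C2) / 2
    G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
    ap1 <- (1 + G) * a1; ap2 <- (1 + G) * a2
    Cp1 <- sqrt(ap1^2 + b1^2); Cp2 <- sqrt(ap2^2 + b2^2)
    hp <- function(ap, b) {
        if (ap == 0 && b == 0) return(0)
        h <- deg(atan2(b, ap))
        if (h < 0) h + 360 else h
    }
    hp1 <- hp(ap1, b1); hp2 <- hp(ap2, b2)
    dLp <- L2 - L1; dCp <- Cp2 - Cp1
    dhp <- if (Cp1 * Cp2 == 0) 0 else {
        d <- hp2 - hp1
        if (d > 180) d - 360 else if (d < -180) d + 360 else d
    }
    dHp <- 2 * sqrt(Cp1 * Cp2) * sin(rad(dhp) / 2)
    Lbar <- (L1 + L2) / 2; Cpbar <- (Cp1 + Cp2) / 2
    hpbar <- if (Cp1 * Cp2 == 0) hp1 + hp2 else {
        s <- hp1 + hp2
        if (abs(hp1 - hp2) <= 180) s / 2
        else if (s < 360) (s + 360) / 2
        else (s - 360) / 2
    }
    T <- 1 - 0.17 * cos(rad(hpbar - 30)) + 0.24 * cos(rad(2 * hpbar)) +
        0.32 * cos(rad(3 * hpbar + 6)) - 0.20 * cos(rad(4 * hpbar - 63))
    dTheta <- 30 * exp(-((hpbar - 275) / 25)^2)
    RC <- 2 * sqrt(Cpbar^7 / (Cpbar^7 + 25^7))
    SL <- 1 + 0.015 * (Lbar - 50)^2 / sqrt(20 + (Lbar - 50)^2)
    SC <- 1 + 0.045 * Cpbar
    SH <- 1 + 0.015 * Cpbar * T
    RT <- -sin(rad(2 * dTheta)) * RC
    sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
         RT * (dCp / SC) * (dHp / SH))
}

# Brute-force scoring: recompute fs, SH, SC, ST directly from the
# definitions for an N x 3 Lab matrix and an N x N distance matrix.
oracle_score <- function(lab, dmat, fc, metric = c("euclidean", "ciede2000")) {
    metric <- match.arg(metric)
    N <- nrow(lab)
    cvals <- c(); dvals <- c()
    for (j in seq_len(N - 1)) {
        for (i in seq(j + 1, N)) {
            cij <- if (metric == "euclidean") sqrt(sum((lab[i, ] - lab[j, ])^2))
                   else oracle_ciede2000(lab[i, ], lab[j, ])
            cvals <- c(cvals, cij)
            dvals <- c(dvals, dmat[i, j])
        }
    }
    n <- N * (N - 1) / 2
    fs <- n / sum(cvals)
    sh <- sum((fs * cvals - dvals)^2)
    sc <- fc / mean(cvals)
    list(fs = fs, sh = sh, sc = sc, st = sh + sc, meanC = mean(cvals))
}

# Brute-force distance matrix from a substitution score table.
oracle_distance <- function(m) {
    N <- nrow(m)
    d <- matrix(0, N, N)
    for (i in seq_len(N)) for (j in seq_len(N)) {
        if (j < i) d[i, j] <- ((m[i, i] - m[i, j]) + (m[j, j] - m[j, i])) / 2
    }
    d / mean(d[lower.tri(d)])
}

# Does each back-converted scheme color satisfy the box constraints up to
# quantization loss? True if the color is a member, or within dE00 < 1 of
# its projection onto the box.
within_quantization <- function(lab, lMin = 0, lMax = 100, aMin = -Inf,
                                aMax = Inf, bMin = -Inf, bMax = Inf) {
    proj <- lab
    proj[, 1] <- pmin(pmax(proj[, 1], lMin), lMax)
    proj[, 2] <- pmin(pmax(proj[, 2], aMin), aMax)
    proj[, 3] <- pmin(pmax(proj[, 3], bMin), bMax)
    ciede2000(lab, proj) < 1
}

# A small subspace and random conformation used by several files.
random_conformation <- function(N, subspace = colorSubspace(60, 75)) {
    colorConformation(LETTERS[seq_len(N)], sampleSubspace(subspace, N))
}

# The 34 published CIEDE2000 reference pairs, bundled with the package
# (columns L1,a1,b1, L2,a2,b2, dE00).
ciede2000_reference <- as.matrix(utils::read.delim(
    system.file("extdata", "ciede2000_reference.tsv",
                package = "MatrixPalette")))
dimnames(ciede2000_reference) <- NULL

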