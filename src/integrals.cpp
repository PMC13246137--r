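// McMurchie-Davidson evaluation of Gaussian integrals over contracted
// Cartesian shells (l <= 2) for any particle kind: overlap, mass-scaled
// kinetic, point-charge Coulomb, and generic two-cloud repulsion tensors.
// The 1/r12 kernel is particle-agnostic; interaction signs are applied by
// the callers in R.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int NCOMP[3] = {1, 3, 6};

// Cartesian component exponents per angular momentum, alphabetical order:
// l=1: x,y,z ; l=2: xx,xy,xz,yy,yz,zz
static const int CART[3][6][3] = {
    {{0,0,0}, {0,0,0}, {0,0,0}, {0,0,0}, {0,0,0}, {0,0,0}},
    {{1,0,0}, {0,1,0}, {0,0,1}, {0,0,0}, {0,0,0}, {0,0,0}},
    {{2,0,0}, {1,1,0}, {1,0,1}, {0,2,0}, {0,1,1}, {0,0,2}}
};

static double dfact(int n) { // (2n-1)!! with dfact(0) = 1
    double r = 1.0;
    for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
    return r;
}

// ---------------------------------------------------------------------------
// Boys function F_n(x) = int_0^1 t^(2n) exp(-x t^2) dt.
// Series + downward recursion for x <= 35, erf closed form + upward
// recursion for large x (protonic exponents routinely reach x ~ 10^2).
// ---------------------------------------------------------------------------
static void boys_array(int nmax, double x, double* F) {
    if (x < 0) stop("boys: x must be >= 0");
    if (x < 1e-14) {
        for (int n = 0; n <= nmax; ++n) F[n] = 1.0 / (2.0 * n + 1.0);
        return;
    }
    const double ex = std::exp(-x);
    if (x > 35.0) {
        F[0] = 0.5 * std::sqrt(M_PI / x) * std::erf(std::sqrt(x));
        for (int n = 1; n <= nmax; ++n)
            F[n] = ((2.0 * n - 1.0) * F[n - 1] - ex) * (0.5 / x);
    } else {
        double term = 1.0 / (2.0 * nmax + 1.0), sum = term;
        for (int k = 1; k < 10000; ++k) {
            term *= 2.0 * x / (2.0 * nmax + 2.0 * k + 1.0);
            sum += term;
            if (term < sum * 1e-17) break;
        }
        F[nmax] = sum * ex;
        for (int n = nmax; n > 0; --n)
            F[n - 1] = (2.0 * x * F[n] + ex) / (2.0 * n - 1.0);
    }
}

// [[Rcpp::export]]
NumericVector boys_cpp(int n, NumericVector x) {
    if (n < 0) stop("boys: n must be a non-negative integer");
    NumericVector out(x.size());
    std::vector<double> F(n + 1);
    for (R_xlen_t i = 0; i < x.size(); ++i) {
        boys_array(n, x[i], F.data());
        out[i] = F[n];
    }
    return out;
}

// ---------------------------------------------------------------------------
// Shell container
// ---------------------------------------------------------------------------
struct Shell {
    double A[3];
    int l, nprim, ncomp, offset;
    std::vector<double> exps;
    std::vector<double> cc;     // contraction coeff * primitive radial norm
    std::vector<double> cscale; // per-component: contracted norm / sqrt(prod dfact)
};

static std::vector<Shell> parse_shells(const List& shells) {
    std::vector<Shell> out;
    out.reserve(shells.size());
    int off = 0;
    for (int is = 0; is < shells.size(); ++is) {
        List sh = shells[is];
        Shell s;
        NumericVector A = sh["center"];
        for (int d = 0; d < 3; ++d) s.A[d] = A[d];
        s.l = as<int>(sh["l"]);
        if (s.l < 0 || s.l > 2) stop("unsupported angular momentum (l > 2)");
        NumericVector e = sh["exponents"], c = sh["coeffs"], nm = sh["norms"];
        s.nprim = e.size();
        s.ncomp = NCOMP[s.l];
        s.exps.resize(s.nprim);
        s.cc.resize(s.nprim);
        for (int k = 0; k < s.nprim; ++k) {
            s.exps[k] = e[k];
            // radial part of the primitive normalization; the component-
            // dependent double-factorial part goes into cscale
            s.cc[k] = c[k] * std::pow(2.0 * e[k] / M_PI, 0.75) *
                      std::pow(4.0 * e[k], 0.5 * s.l);
        }
        s.cscale.resize(s.ncomp);
        for (int m = 0; m < s.ncomp; ++m) {
            const int* q = CART[s.l][m];
            s.cscale[m] = nm[m] / std::sqrt(dfact(q[0]) * dfact(q[1]) * dfact(q[2]));
        }
        s.offset = off;
        off += s.ncomp;
        out.push_back(s);
    }
    return out;
}

static int nbf_total(const std::vector<Shell>& sh) {
    return sh.empty() ? 0 : sh.back().offset + sh.back().ncomp;
}

// ---------------------------------------------------------------------------
// Hermite expansion coefficients E_t^{ij} for one dimension, i <= imax,
// j <= jmax, t <= i + j.  Flat layout E[(i*(jmax+1)+j)*(imax+jmax+1)+t].
// ---------------------------------------------------------------------------
struct ETab {
    int imax, jmax, tdim;
    std::vector<double> v;
    double at(int i, int j, int t) const {
        if (t < 0 || t > i + j) return 0.0;
        return v[(size_t)(i * (jmax + 1) + j) * tdim + t];
    }
    double& ref(int i, int j, int t) {
        return v[(size_t)(i * (jmax + 1) + j) * tdim + t];
    }
};

static void build_E(ETab& E, int imax, int jmax, double a, double b,
                    double AB, double K) {
    E.imax = imax; E.jmax = jmax; E.tdim = imax + jmax + 1;
    E.v.assign((size_t)(imax + 1) * (jmax + 1) * E.tdim, 0.0);
    const double p = a + b, oo2p = 0.5 / p;
    const double PA = -b * AB / p, PB = a * AB / p; // P - A, P - B with AB = A - B
    E.ref(0, 0, 0) = K;
    for (int i = 1; i <= imax; ++i)
        for (int t = 0; t <= i; ++t)
            E.ref(i, 0, t) = oo2p * E.at(i - 1, 0, t - 1) +
                             PA * E.at(i - 1, 0, t) +
                             (t + 1) * E.at(i - 1, 0, t + 1);
    for (int j = 1; j <= jmax; ++j)
        for (int i = 0; i <= imax; ++i)
            for (int t = 0; t <= i + j; ++t)
                E.ref(i, j, t) = oo2p * E.at(i, j - 1, t - 1) +
                                 PB * E.at(i, j - 1, t) +
                                 (t + 1) * E.at(i, j - 1, t + 1);
}

// ---------------------------------------------------------------------------
// Hermite Coulomb integrals R_{tuv} (n = 0 slice) for given p and PC.
// ---------------------------------------------------------------------------
static void hermite_R(int tmax, int umax, int vmax, double p,
                      const double* PC, std::vector<double>& out) {
    const int L = tmax + umax + vmax;
    const int nt = tmax + 1, nu = umax + 1, nv = vmax + 1;
    std::vector<double> R((size_t)(L + 1) * nt * nu * nv, 0.0);
    auto idx = [&](int n, int t, int u, int v) {
        return ((size_t)(n * nt + t) * nu + u) * nv + v;
    };
    const double r2 = PC[0] * PC[0] + PC[1] * PC[1] + PC[2] * PC[2];
    std::vector<double> F(L + 1);
    boys_array(L, p * r2, F.data());
    double m2p = 1.0;
    for (int n = 0; n <= L; ++n) { R[idx(n, 0, 0, 0)] = m2p * F[n]; m2p *= -2.0 * p; }
    for (int t = 1; t <= tmax; ++t)
        for (int n = 0; n <= L - t; ++n)
            R[idx(n, t, 0, 0)] =
                (t > 1 ? (t - 1) * R[idx(n + 1, t - 2, 0, 0)] : 0.0) +
                PC[0] * R[idx(n + 1, t - 1, 0, 0)];
    for (int u = 1; u <= umax; ++u)
        for (int t = 0; t <= tmax; ++t)
            for (int n = 0; n <= L - t - u; ++n)
                R[idx(n, t, u, 0)] =
                    (u > 1 ? (u - 1) * R[idx(n + 1, t, u - 2, 0)] : 0.0) +
                    PC[1] * R[idx(n + 1, t, u - 1, 0)];
    for (int v = 1; v <= vmax; ++v)
        for (int u = 0; u <= umax; ++u)
            for (int t = 0; t <= tmax; ++t)
                for (int n = 0; n <= L - t - u - v; ++n)
                    R[idx(n, t, u, v)] =
                        (v > 1 ? (v - 1) * R[idx(n + 1, t, u, v - 2)] : 0.0) +
                        PC[2] * R[idx(n + 1, t, u, v - 1)];
    out.assign((size_t)nt * nu * nv, 0.0);
    for (int t = 0; t <= tmax; ++t)
        for (int u = 0; u <= umax; ++u)
            for (int v = 0; v <= vmax; ++v)
                out[((size_t)t * nu + u) * nv + v] = R[idx(0, t, u, v)];
}

// ---------------------------------------------------------------------------
// Overlap and kinetic (T scaled by 1/mass)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List overlap_kinetic_cpp(List shells, double mass) {
    std::vector<Shell> sh = parse_shells(shells);
    const int n = nbf_total(sh);
    NumericMatrix S(n, n), T(n, n);
    for (size_t is = 0; is < sh.size(); ++is)
        for (size_t js = 0; js <= is; ++js) {
            const Shell &P = sh[is], &Q = sh[js];
            const int nc1 = P.ncomp, nc2 = Q.ncomp;
            std::vector<double> sblk((size_t)nc1 * nc2, 0.0),
                                tblk((size_t)nc1 * nc2, 0.0);
            for (int ka = 0; ka < P.nprim; ++ka)
                for (int kb = 0; kb < Q.nprim; ++kb) {
                    const double a = P.exps[ka], b = Q.exps[kb], p = a + b;
                    const double cab = P.cc[ka] * Q.cc[kb];
                    const double spf = std::sqrt(M_PI / p);
                    ETab E[3];
                    for (int d = 0; d < 3; ++d) {
                        double AB = P.A[d] - Q.A[d];
                        double K = std::exp(-a * b / p * AB * AB);
                        build_E(E[d], P.l, Q.l + 2, a, b, AB, K);
                    }
                    for (int m1 = 0; m1 < nc1; ++m1)
                        for (int m2 = 0; m2 < nc2; ++m2) {
                            const int* qa = CART[P.l][m1];
                            const int* qb = CART[Q.l][m2];
                            double s1[3], t1[3];
                            for (int d = 0; d < 3; ++d) {
                                const int i = qa[d], j = qb[d];
                                s1[d] = E[d].at(i, j, 0) * spf;
                                double sjp2 = E[d].at(i, j + 2, 0) * spf;
                                double sjm2 = (j >= 2) ? E[d].at(i, j - 2, 0) * spf : 0.0;
                                t1[d] = -2.0 * b * b * sjp2 +
                                        b * (2.0 * j + 1.0) * s1[d] -
                                        0.5 * j * (j - 1.0) * sjm2;
                            }
                            const double w = cab * P.cscale[m1] * Q.cscale[m2];
                            sblk[m1 * nc2 + m2] += w * s1[0] * s1[1] * s1[2];
                            tblk[m1 * nc2 + m2] += w * (t1[0] * s1[1] * s1[2] +
                                                        s1[0] * t1[1] * s1[2] +
                                                        s1[0] * s1[1] * t1[2]);
                        }
                }
            for (int m1 = 0; m1 < nc1; ++m1)
                for (int m2 = 0; m2 < nc2; ++m2) {
                    const int mu = P.offset + m1, nu = Q.offset + m2;
                    S(mu, nu) = S(nu, mu) = sblk[m1 * nc2 + m2];
                    T(mu, nu) = T(nu, mu) = tblk[m1 * nc2 + m2] / mass;
                }
        }
    return List::create(_["S"] = S, _["T"] = T);
}

// ---------------------------------------------------------------------------
// Point-charge Coulomb matrix: sign * sum_A Z_A <mu| 1/|r - R_A| |nu>
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix point_charge_cpp(List shells, NumericMatrix centers,
                               NumericVector charges, double sign) {
    std::vector<Shell> sh = parse_shells(shells);
    const int n = nbf_total(sh), nq = charges.size();
    NumericMatrix V(n, n);
    if (nq == 0) return V;
    std::vector<double> Rt;
    for (size_t is = 0; is < sh.size(); ++is)
        for (size_t js = 0; js <= is; ++js) {
            const Shell &P = sh[is], &Q = sh[js];
            const int nc1 = P.ncomp, nc2 = Q.ncomp;
            std::vector<double> blk((size_t)nc1 * nc2, 0.0);
            for (int ka = 0; ka < P.nprim; ++ka)
                for (int kb = 0; kb < Q.nprim; ++kb) {
                    const double a = P.exps[ka], b = Q.exps[kb], p = a + b;
                    const double cab = P.cc[ka] * Q.cc[kb];
                    double Pc[3];
                    ETab E[3];
                    for (int d = 0; d < 3; ++d) {
                        double AB = P.A[d] - Q.A[d];
                        Pc[d] = (a * P.A[d] + b * Q.A[d]) / p;
                        double K = std::exp(-a * b / p * AB * AB);
                        build_E(E[d], P.l, Q.l, a, b, AB, K);
                    }
                    const int tmax = P.l + Q.l;
                    const double pref = 2.0 * M_PI / p * cab;
                    for (int iq = 0; iq < nq; ++iq) {
                        double PC[3] = {Pc[0] - centers(iq, 0),
                                        Pc[1] - centers(iq, 1),
                                        Pc[2] - centers(iq, 2)};
                        hermite_R(tmax, tmax, tmax, p, PC, Rt);
                        const int nu_ = tmax + 1, nv_ = tmax + 1;
                        for (int m1 = 0; m1 < nc1; ++m1)
                            for (int m2 = 0; m2 < nc2; ++m2) {
                                const int* qa = CART[P.l][m1];
                                const int* qb = CART[Q.l][m2];
                                double acc = 0.0;
                                for (int t = 0; t <= qa[0] + qb[0]; ++t)
                                    for (int u = 0; u <= qa[1] + qb[1]; ++u)
                                        for (int v = 0; v <= qa[2] + qb[2]; ++v)
                                            acc += E[0].at(qa[0], qb[0], t) *
                                                   E[1].at(qa[1], qb[1], u) *
                                                   E[2].at(qa[2], qb[2], v) *
                                                   Rt[((size_t)t * nu_ + u) * nv_ + v];
                                blk[m1 * nc2 + m2] += pref * charges[iq] *
                                    P.cscale[m1] * Q.cscale[m2] * acc;
                            }
                    }
                }
            for (int m1 = 0; m1 < nc1; ++m1)
                for (int m2 = 0; m2 < nc2; ++m2) {
                    const int mu = P.offset + m1, nu2 = Q.offset + m2;
                    V(mu, nu2) = V(nu2, mu) = sign * blk[m1 * nc2 + m2];
                }
        }
    return V;
}

// ---------------------------------------------------------------------------
// Two-cloud repulsion tensor (mu nu | la si), chemist ordering.
// Bra functions from shellsA, ket functions from shellsB; same_kind = true
// exploits full 8-fold symmetry (identical shell lists assumed).
// ---------------------------------------------------------------------------

struct PrimPair {
    double p, P[3], K[3]; // K folded into E tables instead; keep exponents
    double a, b, cab;
};

static void shell_quartet(const Shell& A, const Shell& B,
                          const Shell& C, const Shell& D,
                          std::vector<double>& out) {
    const int nc1 = A.ncomp, nc2 = B.ncomp, nc3 = C.ncomp, nc4 = D.ncomp;
    out.assign((size_t)nc1 * nc2 * nc3 * nc4, 0.0);
    const int lab = A.l + B.l, lcd = C.l + D.l;
    std::vector<double> Rt;
    ETab Eb[3], Ek[3];
    for (int ka = 0; ka < A.nprim; ++ka)
        for (int kb = 0; kb < B.nprim; ++kb) {
            const double a = A.exps[ka], b = B.exps[kb], p = a + b;
            double Pc[3];
            for (int d = 0; d < 3; ++d) {
                const double AB = A.A[d] - B.A[d];
                Pc[d] = (a * A.A[d] + b * B.A[d]) / p;
                build_E(Eb[d], A.l, B.l, a, b, AB,
                        std::exp(-a * b / p * AB * AB));
            }
            const double cab = A.cc[ka] * B.cc[kb];
            for (int kc = 0; kc < C.nprim; ++kc)
                for (int kd = 0; kd < D.nprim; ++kd) {
                    const double c = C.exps[kc], dd = D.exps[kd], q = c + dd;
                    double Qc[3], PQ[3];
                    for (int d = 0; d < 3; ++d) {
                        const double CD = C.A[d] - D.A[d];
                        Qc[d] = (c * C.A[d] + dd * D.A[d]) / q;
                        PQ[d] = Pc[d] - Qc[d];
                        build_E(Ek[d], C.l, D.l, c, dd, CD,
                                std::exp(-c * dd / q * CD * CD));
                    }
                    const double omega = p * q / (p + q);
                    const double pref = 2.0 * std::pow(M_PI, 2.5) /
                        (p * q * std::sqrt(p + q)) * cab * C.cc[kc] * D.cc[kd];
                    hermite_R(lab + lcd, lab + lcd, lab + lcd, omega, PQ, Rt);
                    const int nu_ = lab + lcd + 1, nv_ = lab + lcd + 1;
                    size_t m = 0;
                    for (int m1 = 0; m1 < nc1; ++m1)
                        for (int m2 = 0; m2 < nc2; ++m2)
                            for (int m3 = 0; m3 < nc3; ++m3)
                                for (int m4 = 0; m4 < nc4; ++m4, ++m) {
                                    const int* qa = CART[A.l][m1];
                                    const int* qb = CART[B.l][m2];
                                    const int* qc = CART[C.l][m3];
                                    const int* qd = CART[D.l][m4];
                                    double acc = 0.0;
                                    for (int t = 0; t <= qa[0] + qb[0]; ++t)
                                    for (int u = 0; u <= qa[1] + qb[1]; ++u)
                                    for (int v = 0; v <= qa[2] + qb[2]; ++v) {
                                        const double eb = Eb[0].at(qa[0], qb[0], t) *
                                                          Eb[1].at(qa[1], qb[1], u) *
                                                          Eb[2].at(qa[2], qb[2], v);
                                        if (eb == 0.0) continue;
                                        double acck = 0.0;
                                        for (int t2 = 0; t2 <= qc[0] + qd[0]; ++t2)
                                        for (int u2 = 0; u2 <= qc[1] + qd[1]; ++u2)
                                        for (int v2 = 0; v2 <= qc[2] + qd[2]; ++v2) {
                                            double ek = Ek[0].at(qc[0], qd[0], t2) *
                                                        Ek[1].at(qc[1], qd[1], u2) *
                                                        Ek[2].at(qc[2], qd[2], v2);
                                            if (ek == 0.0) continue;
                                            const double sg = ((t2 + u2 + v2) % 2) ? -1.0 : 1.0;
                                            acck += sg * ek *
                                                Rt[((size_t)(t + t2) * nu_ + (u + u2)) * nv_ + (v + v2)];
                                        }
                                        acc += eb * acck;
                                    }
                                    out[m] += pref * acc *
                                        A.cscale[m1] * B.cscale[m2] *
                                        C.cscale[m3] * D.cscale[m4];
                                }
                }
        }
}

// Schwarz bounds sqrt(max |(ab|ab)|) per shell pair
static std::vector<double> schwarz_bounds(const std::vector<Shell>& sh) {
    const size_t ns = sh.size();
    std::vector<double> Q(ns * ns, 0.0);
    std::vector<double> blk;
    for (size_t i = 0; i < ns; ++i)
        for (size_t j = 0; j <= i; ++j) {
            shell_quartet(sh[i], sh[j], sh[i], sh[j], blk);
            const int nc1 = sh[i].ncomp, nc2 = sh[j].ncomp;
            double mx = 0.0;
            for (int m1 = 0; m1 < nc1; ++m1)
                for (int m2 = 0; m2 < nc2; ++m2) {
                    const size_t m = (((size_t)m1 * nc2 + m2) * nc1 + m1) * nc2 + m2;
                    mx = std::max(mx, std::fabs(blk[m]));
                }
            Q[i * ns + j] = Q[j * ns + i] = std::sqrt(mx);
        }
    return Q;
}

// [[Rcpp::export]]
NumericVector eri_cpp(List shellsA, List shellsB, bool same_kind,
                      double schwarz_thresh) {
    std::vector<Shell> shA = parse_shells(shellsA);
    std::vector<Shell> shB = same_kind ? shA : parse_shells(shellsB);
    const int n1 = nbf_total(shA), n2 = nbf_total(shB);
    NumericVector out((R_xlen_t)n1 * n1 * n2 * n2);
    out.attr("dim") = IntegerVector::create(n1, n1, n2, n2);
    if (n1 == 0 || n2 == 0) return out;
    double* G = out.begin();
    const size_t d1 = n1, d2 = (size_t)n1 * n1, d3 = d2 * n2;
    std::vector<double> QA = schwarz_bounds(shA);
    std::vector<double> QB = same_kind ? QA : schwarz_bounds(shB);
    std::vector<double> blk;
    const size_t nsA = shA.size(), nsB = shB.size();
    auto store = [&](int mu, int nu, int la, int si, double v) {
        G[mu + nu * d1 + la * d2 + si * d3] = v;
        G[nu + mu * d1 + la * d2 + si * d3] = v;
        G[mu + nu * d1 + si * d2 + la * d3] = v;
        G[nu + mu * d1 + si * d2 + la * d3] = v;
    };
    for (size_t i = 0; i < nsA; ++i)
        for (size_t j = 0; j <= i; ++j) {
            const double qij = QA[i * nsA + j];
            for (size_t k = same_kind ? i : (nsB - 1); ; --k) {
                // for same_kind, loop k from i down to 0 with (kl) <= (ij)
                for (size_t l = 0; l <= k; ++l) {
                    if (same_kind && k == i && l > j) break;
                    if (qij * QB[k * nsB + l] < schwarz_thresh) continue;
                    shell_quartet(shA[i], shA[j], shB[k], shB[l], blk);
                    const Shell &Si = shA[i], &Sj = shA[j], &Sk = shB[k], &Sl = shB[l];
                    size_t m = 0;
                    for (int m1 = 0; m1 < Si.ncomp; ++m1)
                        for (int m2 = 0; m2 < Sj.ncomp; ++m2)
                            for (int m3 = 0; m3 < Sk.ncomp; ++m3)
                                for (int m4 = 0; m4 < Sl.ncomp; ++m4, ++m) {
                                    const int mu = Si.offset + m1, nu = Sj.offset + m2;
                                    const int la = Sk.offset + m3, si = Sl.offset + m4;
                                    const double v = blk[m];
                                    store(mu, nu, la, si, v);
                                    if (same_kind) store(la, si, mu, nu, v);
                                }
                }
                if (k == 0) break;
            }
        }
    return out;
}

// Self-overlap diagonal of a single shell (norms taken as supplied),
// used by the R-side normalization pass.
// [[Rcpp::export]]
NumericVector shell_self_overlap_cpp(List shell) {
    List lst = List::create(shell);
    List st = overlap_kinetic_cpp(lst, 1.0);
    NumericMatrix S = st["S"];
    NumericVector d(S.nrow());
    for (int i = 0; i < S.nrow(); ++i) d[i] = S(i, i);
    return d;
}
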