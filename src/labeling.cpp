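#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass union-find connected-component labeling on a column-major mask.
// connectivity: 4 or 8 (8 adds the two diagonal predecessors).

static inline int uf_find(std::vector<int> &par, int x) {
    while (par[x] != x) {
        par[x] = par[par[x]];
        x = par[x];
    }
    return x;
}

static inline void uf_union(std::vector<int> &par, int a, int b) {
    a = uf_find(par, a);
    b = uf_find(par, b);
    if (a < b) par[b] = a; else if (b < a) par[a] = b;
}

// mask: 0/1 values, length nr*nc, column-major. lab receives labels 1..k (0 = bg).
static int label_core(const std::vector<unsigned char> &mask, int nr, int nc,
                      int connectivity, std::vector<int> &lab) {
    std::vector<int> par(1, 0);  // par[0] unused
    int next = 1;
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            int idx = i + nr * j;
            if (!mask[idx]) { lab[idx] = 0; continue; }
            int best = 0;
            int neigh[4];
            int nn = 0;
            if (i > 0 && mask[idx - 1]) neigh[nn++] = lab[idx - 1];
            if (j > 0 && mask[idx - nr]) neigh[nn++] = lab[idx - nr];
            if (connectivity == 8 && j > 0) {
                if (i > 0 && mask[idx - nr - 1]) neigh[nn++] = lab[idx - nr - 1];
                if (i < nr - 1 && mask[idx - nr + 1]) neigh[nn++] = lab[idx - nr + 1];
            }
            for (int k = 0; k < nn; ++k)
                if (best == 0 || neigh[k] < best) best = neigh[k];
            if (best == 0) {
                par.push_back(next);
                lab[idx] = next++;
            } else {
                lab[idx] = best;
                for (int k = 0; k < nn; ++k) uf_union(par, best, neigh[k]);
            }
        }
    }
    // compress to consecutive labels
    std::vector<int> newlab(next, 0);
    int k = 0;
    for (int x = 1; x < next; ++x)
        if (uf_find(par, x) == x) newlab[x] = ++k;
    for (int idx = 0; idx < nr * nc; ++idx)
        if (lab[idx]) lab[idx] = newlab[uf_find(par, lab[idx])];
    return k;
}

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(LogicalMatrix fg, int connectivity) {
    int nr = fg.nrow(), nc = fg.ncol();
    std::vector<unsigned char> mask(nr * nc);
    for (int idx = 0; idx < nr * nc; ++idx) mask[idx] = fg[idx] == TRUE;
    std::vector<int> lab(nr * nc, 0);
    int k = label_core(mask, nr, nc, connectivity, lab);
    IntegerMatrix out(nr, nc);
    for (int idx = 0; idx < nr * nc; ++idx) out[idx] = lab[idx];
    out.attr("n") = k;
    return out;
}

// b0: foreground components (8-connectivity) of size >= min_px;
// b1: background components (4-connectivity) not touching the border.
static void betti_core(const std::vector<unsigned char> &mask, int nr, int nc,
                       int min_px, int &b0, int &b1,
                       std::vector<int> &lab, std::vector<unsigned char> &inv,
                       std::vector<int> &cnt, std::vector<unsigned char> &touch) {
    int k = label_core(mask, nr, nc, 8, lab);
    cnt.assign(k + 1, 0);
    for (int idx = 0; idx < nr * nc; ++idx)
        if (lab[idx]) cnt[lab[idx]]++;
    b0 = 0;
    for (int x = 1; x <= k; ++x)
        if (cnt[x] >= min_px) b0++;
    for (int idx = 0; idx < nr * nc; ++idx) inv[idx] = !mask[idx];
    int kb = label_core(inv, nr, nc, 4, lab);
    touch.assign(kb + 1, 0);
    for (int i = 0; i < nr; ++i) {
        if (lab[i]) touch[lab[i]] = 1;
        if (lab[i + nr * (nc - 1)]) touch[lab[i + nr * (nc - 1)]] = 1;
    }
    for (int j = 0; j < nc; ++j) {
        if (lab[nr * j]) touch[lab[nr * j]] = 1;
        if (lab[nr - 1 + nr * j]) touch[lab[nr - 1 + nr * j]] = 1;
    }
    b1 = 0;
    for (int x = 1; x <= kb; ++x)
        if (!touch[x]) b1++;
}

// [[Rcpp::export(name = ".betti_cpp")]]
IntegerVector betti_cpp(LogicalMatrix fg, int min_px) {
    int nr = fg.nrow(), nc = fg.ncol();
    std::vector<unsigned char> mask(nr * nc), inv(nr * nc);
    for (int idx = 0; idx < nr * nc; ++idx) mask[idx] = fg[idx] == TRUE;
    std::vector<int> lab(nr * nc), cnt;
    std::vector<unsigned char> touch;
    int b0, b1;
    betti_core(mask, nr, nc, min_px, b0, b1, lab, inv, cnt, touch);
    return IntegerVector::create(_["b0"] = b0, _["b1"] = b1);
}

// Full sweep over thresholds t = 0..255 with foreground = {gray < t}.
// [[Rcpp::export(name = ".betti_sweep_cpp")]]
List betti_sweep_cpp(IntegerMatrix img8, int min_px) {
    int nr = img8.nrow(), nc = img8.ncol(), n = nr * nc;
    IntegerVector b0(256), b1(256);
    std::vector<unsigned char> mask(n), inv(n);
    std::vector<int> lab(n), cnt;
    std::vector<unsigned char> touch;
    for (int t = 0; t < 256; ++t) {
        for (int idx = 0; idx < n; ++idx) mask[idx] = img8[idx] < t;
        int v0, v1;
        betti_core(mask, nr, nc, min_px, v0, v1, lab, inv, cnt, touch);
        b0[t] = v0;
        b1[t] = v1;
    }
    return List::create(_["b0"] = b0, _["b1"] = b1);
}
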