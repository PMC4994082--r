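#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <map>

using namespace Rcpp;

// Unbiased expected heterozygosity (Nei 1987) from allele counts.
static double unbiased_het(const std::vector<int>& counts, int n) {
    double ss = 0.0;
    for (size_t i = 0; i < counts.size(); ++i) {
        double p = (double) counts[i] / n;
        ss += p * p;
    }
    return (double) n / (n - 1) * (1.0 - ss);
}

// One Hoppe-urn draw of an allele configuration under the infinite-allele
// model: gene j+1 founds a new allele with probability theta/(theta+j),
// otherwise copies a uniformly chosen earlier gene. Marginally identical to
// a Kingman coalescent with Poisson(theta/2 * branch length) mutations where
// every mutation creates a novel type (Ewens sampling distribution).
static void iam_config(int n, double theta, std::vector<int>& counts) {
    counts.clear();
    for (int j = 0; j < n; ++j) {
        double u = R::unif_rand() * (theta + j);
        if (u < theta || counts.empty()) {
            counts.push_back(1);
        } else {
            int g = (int) (u - theta);       // earlier gene index in [0, j)
            if (g >= j) g = j - 1;           // guard FP edge
            int acc = 0;
            for (size_t a = 0; a < counts.size(); ++a) {
                acc += counts[a];
                if (g < acc) { counts[a] += 1; break; }
            }
        }
    }
}

// [[Rcpp::export]]
List cpp_iam_sims(int n, double theta, int nsims) {
    if (n < 2) stop("need at least 2 genes");
    if (theta <= 0) stop("theta must be positive");
    IntegerVector k(nsims);
    NumericVector he(nsims);
    std::vector<int> counts;
    for (int s = 0; s < nsims; ++s) {
        iam_config(n, theta, counts);
        k[s] = (int) counts.size();
        he[s] = unbiased_het(counts, n);
    }
    return List::create(_["k"] = k, _["he"] = he);
}

// Allele labels (1-based) for a single IAM sample; used to build synthetic
// equilibrium populations gene by gene.
// [[Rcpp::export]]
IntegerVector cpp_iam_sample(int n, double theta) {
    std::vector<int> counts;
    IntegerVector lab(n);
    int ngenes = 0;
    for (int j = 0; j < n; ++j) {
        double u = R::unif_rand() * (theta + j);
        if (u < theta || ngenes == 0) {
            counts.push_back(1);
            lab[j] = (int) counts.size();
        } else {
            int g = (int) (u - theta);
            if (g >= j) g = j - 1;
            int acc = 0;
            for (size_t a = 0; a < counts.size(); ++a) {
                acc += counts[a];
                if (g < acc) { counts[a] += 1; lab[j] = (int) a + 1; break; }
            }
        }
        ngenes++;
    }
    // shuffle so gene order carries no urn history
    for (int j = n - 1; j > 0; --j) {
        int i = (int) (R::unif_rand() * (j + 1));
        std::swap(lab[j], lab[i]);
    }
    return lab;
}

// Kingman coalescent of n genes with Poisson(theta/2 * t) mutations per
// branch; allele state is a repeat count evolving under the two-phase model:
// each mutation steps +-1 with probability p_step, otherwise +-(1+Geom(geom_p))
// (geometric multistep, size >= 1). Returns allele count and unbiased He per
// simulation, allele identity being the integer repeat score.
// [[Rcpp::export]]
List cpp_tpm_sims(int n, double theta, int nsims, double p_step, double geom_p) {
    if (n < 2) stop("need at least 2 genes");
    if (theta <= 0) stop("theta must be positive");
    if (p_step < 0 || p_step > 1) stop("p_step must be in [0,1]");
    if (geom_p <= 0 || geom_p >= 1) stop("geom_p must be in (0,1)");

    int nnode = 2 * n - 1;
    std::vector<double> time(nnode);
    std::vector<int> left(nnode), right(nnode), state(nnode);
    std::vector<int> active(n);
    IntegerVector kv(nsims);
    NumericVector hev(nsims);

    for (int s = 0; s < nsims; ++s) {
        for (int i = 0; i < n; ++i) { time[i] = 0.0; active[i] = i; }
        int nact = n, nxt = n;
        double t = 0.0;
        while (nact > 1) {
            t += R::exp_rand() * 2.0 / ((double) nact * (nact - 1));
            int i = (int) (R::unif_rand() * nact);
            int j = (int) (R::unif_rand() * (nact - 1));
            if (j >= i) j++;
            left[nxt] = active[i];
            right[nxt] = active[j];
            time[nxt] = t;
            // replace lineage i by parent, drop j
            active[i] = nxt;
            active[j] = active[nact - 1];
            nact--; nxt++;
        }
        int root = nnode - 1;
        state[root] = 0;
        // push states root -> leaves (internal nodes created in time order,
        // so iterating downward visits parents before children)
        for (int v = root; v >= n; --v) {
            int ch[2] = {left[v], right[v]};
            for (int c = 0; c < 2; ++c) {
                int u = ch[c];
                double bl = time[v] - time[u];
                int nmut = (int) R::rpois(theta / 2.0 * bl);
                int st = state[v];
                for (int m = 0; m < nmut; ++m) {
                    int step = 1;
                    if (R::unif_rand() >= p_step)
                        step = 1 + (int) R::rgeom(geom_p);
                    st += (R::unif_rand() < 0.5) ? step : -step;
                }
                state[u] = st;
            }
        }
        std::map<int, int> counts;
        for (int i = 0; i < n; ++i) counts[state[i]]++;
        kv[s] = (int) counts.size();
        double ss = 0.0;
        for (std::map<int, int>::iterator it = counts.begin();
             it != counts.end(); ++it) {
            double p = (double) it->second / n;
            ss += p * p;
        }
        hev[s] = (double) n / (n - 1) * (1.0 - ss);
    }
    return List::create(_["k"] = kv, _["he"] = hev);
}
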