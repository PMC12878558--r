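#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured two-deme coalescent, continuous time in generations.
// Deme 0 and deme 1 exist on [0, tdiv) backward in time; at tdiv all
// lineages fall into a single ancestral deme of diploid size ne_anc.
// Coalescence rate within a deme of diploid size Ne with k lineages:
//   k(k-1)/(4 Ne) per generation (rate 1/(2Ne) per pair).
// Backward migration: a lineage currently in deme i jumps to deme j at
// rate m_ij per generation. Uses R's RNG (set.seed() applies).

namespace {

struct Arena {
    std::vector<int> deme, c1, c2;       // deme label, leaf descendants per pop
    std::vector<double> birth;           // time the lineage was created
    std::vector<std::vector<int> > leaves; // leaf ids (only when tracking)
};

// pick index of the r-th (0-based) active lineage lying in deme d
inline int pick_in_deme(const Arena& A, int k, int d, int r) {
    for (int i = 0; i < k; ++i) {
        if (A.deme[i] == d) {
            if (r == 0) return i;
            --r;
        }
    }
    return -1; // unreachable for valid input
}

} // namespace

// Simulate one genealogy. If track_leaves, branch leaf sets are recorded so
// mutations can be dropped; otherwise only (c1, c2, length) per branch is
// accumulated into Tconf. Returns number of branches recorded.
static int sim_one(int n1, int n2, double ne1, double ne2, double ne_anc,
                   double tdiv, double m12, double m21,
                   bool track_leaves, Arena& A,
                   NumericMatrix* Tconf,
                   std::vector<double>* br_len,
                   std::vector<std::vector<int> >* br_leaves,
                   double* total_len) {
    int n = n1 + n2;
    A.deme.resize(n); A.c1.resize(n); A.c2.resize(n); A.birth.resize(n);
    if (track_leaves) A.leaves.assign(n, std::vector<int>());
    for (int i = 0; i < n; ++i) {
        A.deme[i] = (i < n1) ? 0 : 1;
        A.c1[i] = (i < n1) ? 1 : 0;
        A.c2[i] = (i < n1) ? 0 : 1;
        A.birth[i] = 0.0;
        if (track_leaves) { A.leaves[i].clear(); A.leaves[i].push_back(i + 1); }
    }
    int k = n, nrec = 0;
    double t = 0.0;
    if (total_len) *total_len = 0.0;

    // record a dying lineage's branch
    auto record = [&](int idx, double now) {
        double len = now - A.birth[idx];
        if (len > 0) {
            if (Tconf) (*Tconf)(A.c1[idx], A.c2[idx]) += len;
            if (total_len) *total_len += len;
        }
        if (track_leaves) {
            br_len->push_back(len);
            br_leaves->push_back(A.leaves[idx]);
        }
        ++nrec;
    };
    // merge lineages a and b (a < b) at time now
    auto merge = [&](int a, int b, double now) {
        record(a, now); record(b, now);
        A.c1[a] += A.c1[b]; A.c2[a] += A.c2[b];
        A.birth[a] = now;
        if (track_leaves) {
            A.leaves[a].insert(A.leaves[a].end(), A.leaves[b].begin(), A.leaves[b].end());
        }
        // swap-remove b
        int last = k - 1;
        if (b != last) {
            A.deme[b] = A.deme[last]; A.c1[b] = A.c1[last]; A.c2[b] = A.c2[last];
            A.birth[b] = A.birth[last];
            if (track_leaves) A.leaves[b].swap(A.leaves[last]);
        }
        --k;
    };

    // phase 1: two demes, t in [0, tdiv). Deme membership is kept as index
    // lists so migration-heavy runs avoid O(k) scans per event.
    std::vector<int> mem[2];
    std::vector<int> pos_in_mem(n), mem_of(n);
    mem[0].reserve(n); mem[1].reserve(n);
    for (int i = 0; i < n; ++i) {
        int d = A.deme[i];
        pos_in_mem[i] = (int)mem[d].size();
        mem_of[i] = d;
        mem[d].push_back(i);
    }
    auto mem_remove = [&](int slot) {
        int d = mem_of[slot], p = pos_in_mem[slot];
        int last = mem[d].back();
        mem[d][p] = last; pos_in_mem[last] = p;
        mem[d].pop_back();
    };
    auto mem_add = [&](int slot, int d) {
        mem_of[slot] = d;
        pos_in_mem[slot] = (int)mem[d].size();
        mem[d].push_back(slot);
    };
    // merge() swap-removes slot (k-1) into slot b: membership must follow
    auto mem_rename = [&](int from, int to) {
        if (from == to) return;
        int d = mem_of[from], p = pos_in_mem[from];
        mem[d][p] = to; mem_of[to] = d; pos_in_mem[to] = p;
    };
    while (k > 1 && t < tdiv) {
        int k1 = (int)mem[0].size(), k2 = (int)mem[1].size();
        double rc1 = (ne1 > 0) ? k1 * (k1 - 1.0) / (4.0 * ne1) : 0.0;
        double rc2 = (ne2 > 0) ? k2 * (k2 - 1.0) / (4.0 * ne2) : 0.0;
        double rm1 = k1 * m12, rm2 = k2 * m21;
        double R = rc1 + rc2 + rm1 + rm2;
        if (R <= 0) { t = tdiv; break; }
        double dt = ::Rf_rexp(1.0) / R;
        if (t + dt >= tdiv) { t = tdiv; break; }
        t += dt;
        double u = unif_rand() * R;
        if (u < rc1 + rc2) {
            int d = (u < rc1) ? 0 : 1;
            int kd = (d == 0) ? k1 : k2;
            int ra = (int)(unif_rand() * kd); if (ra >= kd) ra = kd - 1;
            int rb = (int)(unif_rand() * (kd - 1)); if (rb >= kd - 1) rb = kd - 2;
            if (rb >= ra) ++rb;
            int a = mem[d][ra], b = mem[d][rb];
            if (a > b) std::swap(a, b);
            mem_remove(b);
            mem_rename(k - 1, b);   // slot k-1 will be renamed to b by merge
            merge(a, b, t);
        } else if (u < rc1 + rc2 + rm1) {
            int r = (int)(unif_rand() * k1); if (r >= k1) r = k1 - 1;
            int slot = mem[0][r];
            A.deme[slot] = 1;
            mem_remove(slot);
            mem_add(slot, 1);
        } else {
            int r = (int)(unif_rand() * k2); if (r >= k2) r = k2 - 1;
            int slot = mem[1][r];
            A.deme[slot] = 0;
            mem_remove(slot);
            mem_add(slot, 0);
        }
    }
    // phase 2: single ancestral deme
    t = (t < tdiv) ? t : tdiv;
    while (k > 1) {
        double R = k * (k - 1.0) / (4.0 * ne_anc);
        t += ::Rf_rexp(1.0) / R;
        int ra = (int)(unif_rand() * k); if (ra >= k) ra = k - 1;
        int rb = (int)(unif_rand() * (k - 1)); if (rb >= k - 1) rb = k - 2;
        if (rb >= ra) ++rb;
        int a = ra < rb ? ra : rb, b = ra < rb ? rb : ra;
        merge(a, b, t);
    }
    return nrec;
}

//' @noRd
// [[Rcpp::export(name = ".coal_branch_config_lengths")]]
NumericMatrix coal_branch_config_lengths(int n1, int n2, double ne1, double ne2,
                                         double ne_anc, double tdiv,
                                         double m12, double m21, int n_sims) {
    NumericMatrix T(n1 + 1, n2 + 1);
    Arena A;
    for (int s = 0; s < n_sims; ++s) {
        sim_one(n1, n2, ne1, ne2, ne_anc, tdiv, m12, m21,
                false, A, &T, NULL, NULL, NULL);
        if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    for (int i = 0; i <= n1; ++i)
        for (int j = 0; j <= n2; ++j) T(i, j) /= n_sims;
    return T;
}

//' @noRd
// [[Rcpp::export(name = ".coal_sim_locus")]]
List coal_sim_locus(int n1, int n2, double ne1, double ne2, double ne_anc,
                    double tdiv, double m12, double m21,
                    double mu, int seq_length) {
    Arena A;
    std::vector<double> br_len;
    std::vector<std::vector<int> > br_leaves;
    double total_len = 0.0;
    sim_one(n1, n2, ne1, ne2, ne_anc, tdiv, m12, m21,
            true, A, NULL, &br_len, &br_leaves, &total_len);

    int nmut = (mu > 0 && total_len > 0)
        ? (int)::Rf_rpois(total_len * mu * (double)seq_length) : 0;
    if (nmut > seq_length) nmut = seq_length; // infinite-sites saturation guard

    // distinct positions 1..seq_length (partial Fisher-Yates via map-free draw)
    IntegerVector pos(nmut);
    if (nmut > 0) {
        std::vector<int> drawn;
        drawn.reserve(nmut);
        while ((int)drawn.size() < nmut) {
            int p = 1 + (int)(unif_rand() * seq_length);
            if (p > seq_length) p = seq_length;
            bool dup = false;
            for (size_t q = 0; q < drawn.size(); ++q)
                if (drawn[q] == p) { dup = true; break; }
            if (!dup) drawn.push_back(p);
        }
        for (int i = 0; i < nmut; ++i) pos[i] = drawn[i];
    }

    // cumulative branch lengths for proportional branch choice
    int nb = (int)br_len.size();
    std::vector<double> cum(nb);
    double acc = 0.0;
    for (int i = 0; i < nb; ++i) { acc += br_len[i]; cum[i] = acc; }

    List carriers(nmut);
    for (int mth = 0; mth < nmut; ++mth) {
        double u = unif_rand() * acc;
        int lo = 0, hi = nb - 1;
        while (lo < hi) {
            int mid = (lo + hi) / 2;
            if (cum[mid] < u) lo = mid + 1; else hi = mid;
        }
        carriers[mth] = wrap(br_leaves[lo]);
    }
    return List::create(_["pos"] = pos, _["carriers"] = carriers,
                        _["total_length"] = total_len);
}
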