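#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <queue>
#include <vector>

// Matching solvers for persistence-diagram distances.  Diagrams are given
// as parallel birth/death vectors of already-normalized points (essential
// deaths mapped to 1), multiplicity expanded by the caller.

namespace {

inline double supCost(double bx, double dx, double by, double dy) {
    return std::max(std::fabs(bx - by), std::fabs(dx - dy));
}

// Hopcroft-Karp maximum matching on a bipartite graph given as adjacency
// lists of the left side; returns the matching size.
struct HopcroftKarp {
    const std::vector<std::vector<int> > &adj;
    int nl, nr;
    std::vector<int> matchL, matchR, dist;
    static const int INF = std::numeric_limits<int>::max();

    HopcroftKarp(const std::vector<std::vector<int> > &a, int nr_)
        : adj(a), nl((int) a.size()), nr(nr_),
          matchL(a.size(), -1), matchR(nr_, -1), dist(a.size(), 0) {}

    bool bfs() {
        std::queue<int> q;
        bool found = false;
        for (int u = 0; u < nl; ++u) {
            if (matchL[u] < 0) { dist[u] = 0; q.push(u); }
            else dist[u] = INF;
        }
        while (!q.empty()) {
            int u = q.front(); q.pop();
            for (int v : adj[u]) {
                int w = matchR[v];
                if (w < 0) found = true;
                else if (dist[w] == INF) { dist[w] = dist[u] + 1; q.push(w); }
            }
        }
        return found;
    }

    bool dfs(int u) {
        for (int v : adj[u]) {
            int w = matchR[v];
            if (w < 0 || (dist[w] == dist[u] + 1 && dfs(w))) {
                matchL[u] = v; matchR[v] = u;
                return true;
            }
        }
        dist[u] = INF;
        return false;
    }

    int run() {
        int m = 0;
        while (bfs())
            for (int u = 0; u < nl; ++u)
                if (matchL[u] < 0 && dfs(u)) ++m;
        return m;
    }
};

// Can every "long" point of side A (diagonal distance > lambda) be matched
// to a distinct point of side B at sup-norm cost <= lambda?
bool coverLong(const std::vector<double> &ab, const std::vector<double> &ad,
               const std::vector<double> &bb, const std::vector<double> &bd,
               double lambda) {
    std::vector<int> longIdx;
    for (size_t i = 0; i < ab.size(); ++i)
        if ((ad[i] - ab[i]) / 2.0 > lambda) longIdx.push_back((int) i);
    if (longIdx.empty()) return true;
    if (bb.empty()) return false;
    std::vector<std::vector<int> > adj(longIdx.size());
    for (size_t u = 0; u < longIdx.size(); ++u) {
        int i = longIdx[u];
        for (size_t v = 0; v < bb.size(); ++v)
            if (supCost(ab[i], ad[i], bb[v], bd[v]) <= lambda)
                adj[u].push_back((int) v);
        if (adj[u].empty()) return false;
    }
    HopcroftKarp hk(adj, (int) bb.size());
    return hk.run() == (int) longIdx.size();
}

// A bottleneck matching at threshold lambda exists iff the long points of
// each diagram can separately be matched into the other diagram at cost
// <= lambda (Mendelsohn-Dulmage: two one-sided saturating matchings merge
// into one matching saturating both sides; short points fall to their own
// diagonal projections and surplus diagonal slots pair at cost 0).
bool feasible(const std::vector<double> &xb, const std::vector<double> &xd,
              const std::vector<double> &yb, const std::vector<double> &yd,
              double lambda) {
    return coverLong(xb, xd, yb, yd, lambda) &&
           coverLong(yb, yd, xb, xd, lambda);
}

} // namespace

// Exact bottleneck distance between two persistence diagrams with diagonal
// augmentation: binary search over the finite candidate set (all pairwise
// sup-norm costs and all diagonal-projection costs) with a bipartite
// feasibility test at each candidate.
// [[Rcpp::export]]
double bottleneck_cpp(Rcpp::NumericVector xb, Rcpp::NumericVector xd,
                      Rcpp::NumericVector yb, Rcpp::NumericVector yd) {
    std::vector<double> XB(xb.begin(), xb.end()), XD(xd.begin(), xd.end());
    std::vector<double> YB(yb.begin(), yb.end()), YD(yd.begin(), yd.end());
    const size_t nx = XB.size(), ny = YB.size();
    if (nx == 0 && ny == 0) return 0.0;
    std::vector<double> cand;
    cand.reserve(nx * ny + nx + ny + 1);
    cand.push_back(0.0);
    for (size_t i = 0; i < nx; ++i) cand.push_back((XD[i] - XB[i]) / 2.0);
    for (size_t j = 0; j < ny; ++j) cand.push_back((YD[j] - YB[j]) / 2.0);
    for (size_t i = 0; i < nx; ++i)
        for (size_t j = 0; j < ny; ++j)
            cand.push_back(supCost(XB[i], XD[i], YB[j], YD[j]));
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    size_t lo = 0, hi = cand.size() - 1;
    // the largest candidate is always feasible (everything to the diagonal)
    while (lo < hi) {
        size_t mid = lo + (hi - lo) / 2;
        if (feasible(XB, XD, YB, YD, cand[mid])) hi = mid;
        else lo = mid + 1;
    }
    return cand[lo];
}

// O(n^3) Hungarian algorithm (potentials + shortest augmenting paths) for a
// square min-cost assignment; a is n x n in row-major order.
static double hungarian(const std::vector<double> &a, int n) {
    if (n == 0) return 0.0;
    const double INF = std::numeric_limits<double>::infinity();
    std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0), minv(n + 1, 0.0);
    std::vector<int> p(n + 1, 0), way(n + 1, 0);
    std::vector<char> used(n + 1, 0);
    for (int i = 1; i <= n; ++i) {
        p[0] = i;
        int j0 = 0;
        std::fill(minv.begin(), minv.end(), INF);
        std::fill(used.begin(), used.end(), 0);
        do {
            used[j0] = 1;
            int i0 = p[j0], j1 = -1;
            double delta = INF;
            for (int j = 1; j <= n; ++j) {
                if (used[j]) continue;
                double cur = a[(i0 - 1) * n + (j - 1)] - u[i0] - v[j];
                if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
                if (minv[j] < delta) { delta = minv[j]; j1 = j; }
            }
            for (int j = 0; j <= n; ++j) {
                if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
                else minv[j] -= delta;
            }
            j0 = j1;
        } while (p[j0] != 0);
        do {
            int j1 = way[j0];
            p[j0] = p[j1];
            j0 = j1;
        } while (j0);
    }
    double cost = 0.0;
    for (int j = 1; j <= n; ++j)
        cost += a[(p[j] - 1) * n + (j - 1)];
    return cost;
}

// q-Wasserstein distance between two diagrams: min-cost assignment on the
// diagonal-augmented (nx+ny) x (nx+ny) problem with cost ||.||_inf^q, then
// the q-th root of the optimum.
// [[Rcpp::export]]
double wasserstein_cpp(Rcpp::NumericVector xb, Rcpp::NumericVector xd,
                       Rcpp::NumericVector yb, Rcpp::NumericVector yd,
                       double q) {
    const int nx = xb.size(), ny = yb.size();
    const int n = nx + ny;
    if (n == 0) return 0.0;
    std::vector<double> a((size_t) n * n, 0.0);
    for (int i = 0; i < nx; ++i) {
        double proj = std::pow((xd[i] - xb[i]) / 2.0, q);
        for (int j = 0; j < ny; ++j)
            a[(size_t) i * n + j] = std::pow(supCost(xb[i], xd[i], yb[j], yd[j]), q);
        for (int j = ny; j < n; ++j)
            a[(size_t) i * n + j] = proj;   // any diagonal slot
    }
    for (int i = nx; i < n; ++i) {
        for (int j = 0; j < ny; ++j)
            a[(size_t) i * n + j] = std::pow((yd[j] - yb[j]) / 2.0, q);
        // diagonal-to-diagonal stays 0
    }
    double best = hungarian(a, n);
    return std::pow(best, 1.0 / q);
}
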