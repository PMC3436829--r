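#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Damped sum-product belief propagation on a discrete ternary factor graph.
//
// Evidence enters as unary potentials; many independent evidence columns
// (samples, permutation replicates) share one graph structure and are
// solved in a single call.  Messages are stored as (ncol x 3) matrices so
// that per-state vectors over evidence columns are contiguous in memory.
//
// factors: list of list(vars = 0-based IntegerVector,
//                       table = NumericVector of length 3^k, first var fastest)
// potentials: (3 * nvar) x ncol matrix, rows [3v, 3v+2] belong to variable v.

static const int S = 3; // ternary state space

// [[Rcpp::export(name = ".bp_engine")]]
List bp_engine(int nvar, List factors, arma::mat potentials,
               double tol, int max_iter, double damping) {
  const int nf = factors.size();
  const int ncol = potentials.n_cols;

  std::vector< std::vector<int> > fvars(nf);
  std::vector<arma::vec> ftab(nf);
  int max_k = 1;
  for (int f = 0; f < nf; ++f) {
    List ff = factors[f];
    IntegerVector v = ff["vars"];
    fvars[f] = std::vector<int>(v.begin(), v.end());
    NumericVector t = ff["table"];
    ftab[f] = arma::vec(t.begin(), t.size());
    if ((int)fvars[f].size() > max_k) max_k = fvars[f].size();
  }

  // Reshape each factor table, per scope position p, into a
  // (3^(k-1) x 3) matrix Wp with Wp(combo, s) = table entry where
  // variable p is in state s and the remaining scope variables (in
  // ascending position order, first fastest) form `combo`.  The
  // factor->variable message is then the dgemm  M * Wp  with M the
  // (ncol x 3^(k-1)) matrix of products of the other incoming messages.
  std::vector< std::vector<arma::mat> > W(nf);
  for (int f = 0; f < nf; ++f) {
    const int k = fvars[f].size();
    const int T = ftab[f].n_elem;
    const int Tm1 = T / S;
    W[f].assign(k, arma::mat(Tm1, S));
    std::vector<int> st(k);
    for (int t = 0; t < T; ++t) {
      int tmp = t;
      for (int q = 0; q < k; ++q) { st[q] = tmp % S; tmp /= S; }
      for (int p = 0; p < k; ++p) {
        int combo = 0, mult = 1;
        for (int q = 0; q < k; ++q) {
          if (q == p) continue;
          combo += st[q] * mult;
          mult *= S;
        }
        W[f][p](combo, st[p]) = ftab[f][t];
      }
    }
  }

  // transposed potentials per variable: (ncol x 3), contiguous states
  std::vector<arma::mat> pot(nvar);
  for (int v = 0; v < nvar; ++v)
    pot[v] = potentials.rows(3 * v, 3 * v + 2).t();

  // variable -> incident (factor, position) pairs
  std::vector< std::vector< std::pair<int,int> > > adj(nvar);
  for (int f = 0; f < nf; ++f)
    for (size_t p = 0; p < fvars[f].size(); ++p)
      adj[fvars[f][p]].push_back(std::make_pair(f, (int)p));

  std::vector< std::vector<arma::mat> > F2V(nf), V2F(nf), OUT(nf);
  for (int f = 0; f < nf; ++f) {
    int k = fvars[f].size();
    F2V[f].assign(k, arma::mat(ncol, S, arma::fill::value(1.0 / S)));
    V2F[f].assign(k, arma::mat(ncol, S, arma::fill::value(1.0 / S)));
    OUT[f].assign(k, arma::mat(ncol, S, arma::fill::zeros));
  }

  const int max_combo = (int)std::pow((double)S, max_k - 1);
  arma::mat M(ncol, max_combo);
  std::vector<int> others(max_k);

  arma::vec colchange(ncol), norm(ncol);
  arma::mat belief(ncol, S), chg(ncol, S);
  IntegerVector iters(ncol, NA_INTEGER);
  int it;
  bool all_done = (nf == 0);

  for (it = 1; it <= max_iter && !all_done; ++it) {
    colchange.zeros();

    // variable -> factor messages: belief / incoming (fallback: product)
    for (int v = 0; v < nvar; ++v) {
      const int d = adj[v].size();
      if (d == 0) continue;
      belief = pot[v];
      for (int b = 0; b < d; ++b)
        belief %= F2V[adj[v][b].first][adj[v][b].second];
      for (int a = 0; a < d; ++a) {
        const arma::mat &inc = F2V[adj[v][a].first][adj[v][a].second];
        arma::mat &out = V2F[adj[v][a].first][adj[v][a].second];
        if (d == 1) {
          out = pot[v];
        } else if (inc.min() > 1e-290) {
          out = belief / inc;
        } else { // rebuild directly to dodge division by ~0
          out = pot[v];
          for (int b = 0; b < d; ++b) {
            if (b == a) continue;
            out %= F2V[adj[v][b].first][adj[v][b].second];
          }
        }
        norm = arma::sum(out, 1);
        norm.elem(arma::find(norm <= 0)).fill(1.0);
        out.each_col() /= norm;
      }
    }

    // factor -> variable messages:  OUT[p] = M * Wp  with M the combo
    // products of the other incoming messages, built level-wise so each
    // level reuses the previous level's partial products
    for (int f = 0; f < nf; ++f) {
      const int k = fvars[f].size();
      const int Tm1 = (int)W[f][0].n_rows;
      for (int p = 0; p < k; ++p) {
        int no = 0;
        for (int q = 0; q < k; ++q) if (q != p) others[no++] = q;
        if (no == 0) {
          OUT[f][p] = arma::repmat(W[f][p], ncol, 1);
        } else {
          int width = S;
          for (int s = 0; s < S; ++s)
            M.col(s) = V2F[f][others[0]].unsafe_col(s);
          for (int j = 1; j < no; ++j) {
            // expand in place: combo' = combo + s * width; the s = 0
            // block aliases the source columns, so update it last
            for (int s = S - 1; s >= 1; --s)
              for (int c = width - 1; c >= 0; --c)
                M.col(s * width + c) =
                  M.col(c) % V2F[f][others[j]].unsafe_col(s);
            for (int c = 0; c < width; ++c)
              M.col(c) %= V2F[f][others[j]].unsafe_col(0);
            width *= S;
          }
          OUT[f][p] = M.cols(0, Tm1 - 1) * W[f][p];
        }
        arma::mat &out = OUT[f][p];
        norm = arma::sum(out, 1);
        norm.elem(arma::find(norm <= 0)).fill(1.0);
        out.each_col() /= norm;
        out = damping * F2V[f][p] + (1.0 - damping) * out;
        chg = arma::abs(out - F2V[f][p]);
        colchange = arma::max(colchange, arma::max(chg, 1));
        F2V[f][p] = out;
      }
    }

    all_done = true;
    for (int c = 0; c < ncol; ++c) {
      if (colchange[c] < tol) {
        if (iters[c] == NA_INTEGER) iters[c] = it;
      } else {
        iters[c] = NA_INTEGER; // must re-settle if it bounced back up
        all_done = false;
      }
    }
  }

  // final beliefs
  arma::mat marg(S * nvar, ncol);
  for (int v = 0; v < nvar; ++v) {
    belief = pot[v];
    for (size_t b = 0; b < adj[v].size(); ++b)
      belief %= F2V[adj[v][b].first][adj[v][b].second];
    norm = arma::sum(belief, 1);
    norm.elem(arma::find(norm <= 0)).fill(1.0);
    belief.each_col() /= norm;
    marg.rows(3 * v, 3 * v + 2) = belief.t();
  }

  LogicalVector converged(ncol);
  IntegerVector iters_out(ncol);
  for (int c = 0; c < ncol; ++c) {
    converged[c] = (iters[c] != NA_INTEGER) || nf == 0;
    iters_out[c] = (iters[c] == NA_INTEGER) ? (nf == 0 ? 0 : it - 1) : iters[c];
  }

  return List::create(_["marginals"] = marg,
                      _["iterations"] = iters_out,
                      _["converged"] = converged);
}
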