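// Core dynamics of the variance-predicting recurrent network.
//
// One exported routine runs a whole sequence: leaky-integrator context
// update, mean/variance output heads, Gaussian negative log-likelihood,
// precision-weighted fusion of prediction and sensory sample, and (on
// request) backpropagation-through-time gradients for all weights and the
// initial context state.  Gradients flow through the recurrent context
// path, the output heads, and the input pathway: when the input of step t
// is the fused posterior (or the fed-back prediction), its dependence on
// the step-t prediction is part of the backward pass, so the network
// learns the stability of its own feedback loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Net {
  arma::mat W_in;    // N x D
  arma::mat W_rec;   // N x N
  arma::vec b_ctx;   // N
  arma::mat W_mu;    // D x N
  arma::vec b_mu;    // D
  arma::mat W_var;   // D x N
  arma::vec b_var;   // D
  double tau;
  double var_floor;
};

Net unpack(const List& p) {
  Net n;
  n.W_in      = as<arma::mat>(p["W_in"]);
  n.W_rec     = as<arma::mat>(p["W_rec"]);
  n.b_ctx     = as<arma::vec>(p["b_ctx"]);
  n.W_mu      = as<arma::mat>(p["W_mu"]);
  n.b_mu      = as<arma::vec>(p["b_mu"]);
  n.W_var     = as<arma::mat>(p["W_var"]);
  n.b_var     = as<arma::vec>(p["b_var"]);
  n.tau       = as<double>(p["tau"]);
  n.var_floor = as<double>(p["var_floor"]);
  return n;
}

}  // namespace

// mode: 0 = teacher forcing (input t is the raw sample x[t]),
//       1 = posterior      (input t is the fused posterior mean),
//       2 = closed         (posterior while t <= n_obs, then the network's
//                           own predicted mean; loss only over t <= n_obs).
// h_loss scales the prediction variance inside the NLL (recognition uses
// the prior precision factor there; training uses 1).
// noise: optional T x D matrix of standard-normal draws; when supplied, the
// fused input of step t is a reparameterized sample
// mu_post + sqrt(sigma_post^2) * eps_t from the posterior instead of its
// mean (the stochastic training input; the drawn output stays the mean).
// [[Rcpp::export]]
List sctrnn_run_cpp(List params, arma::vec u0, arma::mat x,
                    int mode, int n_obs,
                    double h_prior, double h_sensor, arma::vec sigma_sensor2,
                    double h_loss, bool want_grad, arma::mat noise) {
  const Net net = unpack(params);
  const int T = x.n_rows;
  const int D = x.n_cols;
  const int N = net.W_rec.n_rows;
  const double rho = 1.0 - 1.0 / net.tau;
  const double inv_tau = 1.0 / net.tau;

  if ((int)sigma_sensor2.n_elem == 1 && D > 1)
    sigma_sensor2 = arma::vec(D, arma::fill::value(sigma_sensor2(0)));
  const int n_loss = (mode == 2) ? std::min(n_obs, T) : T;
  const bool stochastic = noise.n_rows > 0;
  if (stochastic && ((int)noise.n_rows != T || (int)noise.n_cols != D))
    stop("noise matrix must match the input dimensions");

  arma::mat C(N, T);            // C.col(t-1) = context used for prediction t
  arma::mat MU(D, T), S2(D, T), DRAWN(D, T);
  arma::mat XI(D, std::max(T - 1, 1), arma::fill::zeros);

  arma::vec u = u0;
  arma::vec c = arma::tanh(u);
  double nll = 0.0;

  for (int t = 1; t <= T; ++t) {
    C.col(t - 1) = c;
    arma::vec mu = arma::tanh(net.W_mu * c + net.b_mu);
    arma::vec s2 = arma::exp(net.W_var * c + net.b_var) + net.var_floor;
    MU.col(t - 1) = mu;
    S2.col(t - 1) = s2;
    if (!mu.is_finite() || !s2.is_finite())
      stop("non-finite network state at step %d", t);

    arma::vec xt = x.row(t - 1).t();
    if (t <= n_loss) {
      arma::vec sl = h_loss * s2;
      nll += arma::accu(arma::log(2.0 * M_PI * sl) +
                        arma::square(xt - mu) / (2.0 * sl));
    }

    // drawn output: posterior mean while a sensory sample exists,
    // the raw prediction afterwards
    arma::vec vpost;
    if (mode != 2 || t <= n_obs) {
      arma::vec vp = h_prior * s2;
      arma::vec vs = h_sensor * sigma_sensor2;
      vpost = (vs % vp) / (vs + vp);
      DRAWN.col(t - 1) = vpost % (mu / vp + xt / vs);
    } else {
      DRAWN.col(t - 1) = mu;
    }

    if (t < T) {
      arma::vec xi;
      if (mode == 0)       xi = xt;
      else                 xi = DRAWN.col(t - 1);  // posterior mean / fed-back mu
      if (stochastic && (mode != 2 || t <= n_obs))
        xi += arma::sqrt(vpost) % noise.row(t - 1).t();
      XI.col(t - 1) = xi;
      u = rho * u + inv_tau * (net.W_in * xi + net.W_rec * c + net.b_ctx);
      c = arma::tanh(u);
      if (!u.is_finite())
        stop("non-finite context propagation at step %d", t + 1);
    }
  }

  List out = List::create(
      _["mu"] = MU.t(), _["sigma2"] = S2.t(), _["drawn"] = DRAWN.t(),
      _["inputs"] = XI.t(), _["nll"] = nll);

  if (!want_grad) return out;

  // backward pass (inputs XI treated as constants)
  arma::mat gW_in(N, D, arma::fill::zeros);
  arma::mat gW_rec(N, N, arma::fill::zeros);
  arma::vec gb_ctx(N, arma::fill::zeros);
  arma::mat gW_mu(D, N, arma::fill::zeros);
  arma::vec gb_mu(D, arma::fill::zeros);
  arma::mat gW_var(D, N, arma::fill::zeros);
  arma::vec gb_var(D, arma::fill::zeros);

  arma::vec du_next(N, arma::fill::zeros);  // dL/du^{(t)} for current t
  for (int t = T; t >= 1; --t) {
    arma::vec ct = C.col(t - 1);
    arma::vec mu = MU.col(t - 1);
    arma::vec s2 = S2.col(t - 1);
    arma::vec xt = x.row(t - 1).t();
    arma::vec dmu(D, arma::fill::zeros);
    arma::vec ds2(D, arma::fill::zeros);
    if (t <= n_loss) {
      arma::vec err = xt - mu;
      dmu += -err / (h_loss * s2);
      ds2 += 1.0 / s2 - arma::square(err) / (2.0 * h_loss * arma::square(s2));
    }
    if (mode != 0 && t < T) {
      // the input of update t was built from the step-t prediction:
      // xi = (vs mu + vp x) / (vs + vp) [+ sqrt(vpost) eps] in the fused
      // region, xi = mu beyond
      arma::vec dxi = inv_tau * (net.W_in.t() * du_next);
      if (mode == 1 || t <= n_obs) {
        arma::vec vp = h_prior * s2;
        arma::vec vs = h_sensor * sigma_sensor2;
        arma::vec denom = vs + vp;
        dmu += dxi % (vs / denom);
        ds2 += h_prior * (dxi % (vs % (xt - mu) / arma::square(denom)));
        if (stochastic) {
          arma::vec vpost = (vs % vp) / denom;
          // d vpost / d vp = (vs / denom)^2, and d vp / d s2 = h_prior
          ds2 += h_prior * (dxi % noise.row(t - 1).t() %
                            arma::square(vs / denom) / (2.0 * arma::sqrt(vpost)));
        }
      } else {
        dmu += dxi;
      }
    }
    arma::vec dc(N, arma::fill::zeros);
    if (arma::any(dmu != 0.0) || arma::any(ds2 != 0.0)) {
      arma::vec da_mu = dmu % (1.0 - arma::square(mu));
      arma::vec da_v = ds2 % (s2 - net.var_floor);  // d s2 / d a_v = exp(a_v)
      gW_mu += da_mu * ct.t();
      gb_mu += da_mu;
      gW_var += da_v * ct.t();
      gb_var += da_v;
      dc += net.W_mu.t() * da_mu + net.W_var.t() * da_v;
    }
    if (t < T) {
      // update t consumed c_t and produced u^{(t)}
      dc += inv_tau * (net.W_rec.t() * du_next);
      gW_in += inv_tau * (du_next * XI.col(t - 1).t());
      gW_rec += inv_tau * (du_next * ct.t());
      gb_ctx += inv_tau * du_next;
    }
    // u^{(t-1)} feeds c_t through tanh and u^{(t)} through the leak
    du_next = dc % (1.0 - arma::square(ct)) + rho * du_next;
  }

  out["grads"] = List::create(
      _["W_in"] = gW_in, _["W_rec"] = gW_rec, _["b_ctx"] = gb_ctx,
      _["W_mu"] = gW_mu, _["b_mu"] = gb_mu,
      _["W_var"] = gW_var, _["b_var"] = gb_var,
      _["u0"] = du_next);
  return out;
}
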