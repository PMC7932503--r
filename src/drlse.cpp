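// Distance-regularized level-set evolution (double-well potential,
// edge-indicator driven) -- the inner iteration of the lumen segmenter.
// phi < 0 inside the evolving region; a negative balloon coefficient
// expands the region outward until the edge indicator stops it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// central-difference gradient, one-sided at borders
// fx: d/d(col), fy: d/d(row)
static void gradient2(const mat& f, mat& fx, mat& fy) {
  const uword nr = f.n_rows, nc = f.n_cols;
  fx.set_size(nr, nc);
  fy.set_size(nr, nc);
  fx.col(0) = f.col(1) - f.col(0);
  fx.col(nc - 1) = f.col(nc - 1) - f.col(nc - 2);
  if (nc > 2) fx.cols(1, nc - 2) = (f.cols(2, nc - 1) - f.cols(0, nc - 3)) / 2.0;
  fy.row(0) = f.row(1) - f.row(0);
  fy.row(nr - 1) = f.row(nr - 1) - f.row(nr - 2);
  if (nr > 2) fy.rows(1, nr - 2) = (f.rows(2, nr - 1) - f.rows(0, nr - 3)) / 2.0;
}

static mat divergence(const mat& a, const mat& b) {
  mat ax, ay, bx, by;
  gradient2(a, ax, ay);
  gradient2(b, bx, by);
  return ax + by;
}

// 5-point Laplacian with replicated borders
static mat laplacian(const mat& f) {
  const uword nr = f.n_rows, nc = f.n_cols;
  mat up = f, down = f, left = f, right = f;
  up.rows(0, nr - 2) = f.rows(1, nr - 1);
  down.rows(1, nr - 1) = f.rows(0, nr - 2);
  left.cols(0, nc - 2) = f.cols(1, nc - 1);
  right.cols(1, nc - 1) = f.cols(0, nc - 2);
  return up + down + left + right - 4.0 * f;
}

// mirror boundary condition on the level-set function
static void neumannBound(mat& phi) {
  const uword nr = phi.n_rows, nc = phi.n_cols;
  phi(0, 0) = phi(2, 2);
  phi(0, nc - 1) = phi(2, nc - 3);
  phi(nr - 1, 0) = phi(nr - 3, 2);
  phi(nr - 1, nc - 1) = phi(nr - 3, nc - 3);
  phi(span(0, 0), span(1, nc - 2)) = phi(span(2, 2), span(1, nc - 2));
  phi(span(nr - 1, nr - 1), span(1, nc - 2)) = phi(span(nr - 3, nr - 3), span(1, nc - 2));
  phi(span(1, nr - 2), span(0, 0)) = phi(span(1, nr - 2), span(2, 2));
  phi(span(1, nr - 2), span(nc - 1, nc - 1)) = phi(span(1, nr - 2), span(nc - 3, nc - 3));
}

// [[Rcpp::export(name = ".drlseEvolve")]]
Rcpp::List drlseEvolve(arma::mat phi, const arma::mat& g,
                       double mu, double lambda, double alpha,
                       double epsilon, double timestep,
                       int maxIter, int checkEvery, double convTol) {
  const double pi = 3.14159265358979323846;
  mat vx, vy;
  gradient2(g, vx, vy);
  umat signPrev = (phi > 0);
  int used = maxIter;
  double residual = 1.0;
  bool converged = false;

  for (int k = 1; k <= maxIter; ++k) {
    neumannBound(phi);
    mat px, py;
    gradient2(phi, px, py);
    mat s = sqrt(px % px + py % py);
    mat Nx = px / (s + 1e-10);
    mat Ny = py / (s + 1e-10);
    mat curv = divergence(Nx, Ny);

    // double-well distance regularization: p'(s)/s with the 0/0 -> 1 fix
    mat a = conv_to<mat>::from(s <= 1.0);
    mat ps = a % sin(2.0 * pi * s) / (2.0 * pi) + (1.0 - a) % (s - 1.0);
    mat dps = (ps + conv_to<mat>::from(ps == 0.0)) /
              (s + conv_to<mat>::from(s == 0.0));
    mat distReg = divergence(dps % px - px, dps % py - py) + laplacian(phi);

    mat dirac = (0.5 / epsilon) * (1.0 + cos(pi * phi / epsilon));
    dirac = dirac % conv_to<mat>::from(abs(phi) <= epsilon);

    mat areaTerm = dirac % g;
    mat edgeTerm = dirac % (vx % Nx + vy % Ny) + areaTerm % curv;

    phi += timestep * (mu * distReg + lambda * edgeTerm + alpha * areaTerm);

    if (k % checkEvery == 0) {
      umat signNow = (phi > 0);
      residual = accu(signNow != signPrev) / (double)phi.n_elem;
      signPrev = signNow;
      if (residual <= convTol) {
        used = k;
        converged = true;
        break;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("phi") = phi,
                            Rcpp::Named("iterations") = used,
                            Rcpp::Named("residual") = residual,
                            Rcpp::Named("converged") = converged);
}
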