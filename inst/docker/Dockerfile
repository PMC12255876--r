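# Minimal container recipe. The service also runs bare via:
#   Rscript -e 'onehop::serve_http(onehop::build_service(onehop::load_configs("app/config")), port = 8080, host = "0.0.0.0")'
FROM rocker/r2u:jammy

RUN install2.r --error data.table jsonlite yaml digest httpuv optparse

COPY . /opt/onehop
WORKDIR /opt/onehop
RUN R CMD INSTALL --no-docs .

# KG config files are mounted or baked in under /opt/onehop/app/config;
# indexes are built at image build time and persisted into the image so
# container start only re-loads them.
RUN mkdir -p /opt/onehop/app/config /opt/onehop/app/snapshots
RUN Rscript -e 'cfg <- try(onehop::load_configs("app/config"), silent = TRUE); \
  if (!inherits(cfg, "try-error")) invisible(onehop::build_service(cfg, snapshot_dir = "app/snapshots"))'

EXPOSE 8080
CMD ["Rscript", "-e", "onehop::serve_http(onehop::build_service(onehop::load_configs('app/config'), snapshot_dir = 'app/snapshots'), port = 8080, host = '0.0.0.0')"]
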