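# application configuration (generated; edit the model, not this file)
application = ${Name(model)}
entities = ${csv(model.entities, Name)}
api_base = /api/v1
page_limit_max = 1000
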