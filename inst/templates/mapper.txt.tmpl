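# data mapper for entity ${Name(entity)} (generated)
table = ${Name(entity)}
columns = ${csv(entity.fields, Name)}
sql_types = ${csv(entity.fields, sql_type, ; )}
insert = INSERT INTO ${Name(entity)} (${csv(entity.fields, Name)}) VALUES (...)
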