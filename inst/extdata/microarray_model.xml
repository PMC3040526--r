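<molgenis name="microarray">
  <entity name="Experiment" description="A microbe stress experiment">
    <field name="ID" unique="true" readonly="true"/>
    <field name="Title"/>
    <field name="Description" type="text" nillable="true"/>
    <field name="Medium"/>
    <field name="Stress"/>
    <field name="ExperimentDate" type="date" nillable="true"/>
  </entity>
  <entity name="Sample" description="A biological sample taken from an experiment">
    <field name="ID" unique="true" readonly="true"/>
    <field name="Experiment" type="xref" xref_entity="Experiment" xref_field="ID"/>
    <field name="Material"/>
    <field name="OD600" type="decimal" nillable="true"/>
  </entity>
  <entity name="Hybridization" description="A sample hybridized onto an array">
    <field name="ID" unique="true" readonly="true"/>
    <field name="Experiment" type="xref" xref_entity="Experiment" xref_field="ID"/>
    <field name="Sample" type="xref" xref_entity="Sample" xref_field="ID"/>
    <field name="ArrayType"/>
  </entity>
  <ui>
    <plugin name="header" id="app.header"/>
    <form name="Experiments" entity="Experiment">
      <menu name="details">
        <form name="Samples" entity="Sample" view="list"/>
        <form name="Hybridizations" entity="Hybridization" view="list"/>
      </menu>
    </form>
  </ui>
</molgenis>
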