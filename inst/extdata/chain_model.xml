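<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="chain" fbc:strict="true">
    <listOfCompartments>
      <compartment id="e0" name="extracellular" constant="true"/>
      <compartment id="c0" name="cytosol" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="glc_e" name="D-glucose" compartment="e0"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
      <species id="c" name="carbon currency" compartment="c0"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_ex_glc" value="-10" constant="true"/>
      <parameter id="ub_default" value="1000" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_glc" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_ex_glc" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="CAT_glc" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="c" stoichiometry="0.1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="BIOMASS" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="BIOMASS" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
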