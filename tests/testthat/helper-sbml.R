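# A minimal SBML L3V1 document template used by the import tests. The
# kinetic math, extra model-level lists and reaction attributes are
# injectable so single features can be toggled.
minimal_sbml <- function(kinetic_math =
                           '<apply><times/><ci>k1</ci><ci>A</ci></apply>',
                         extra_model = "", reaction_attrs = 'fast="false"') {
  sprintf('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="mini">
    <listOfCompartments>
      <compartment id="cell" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" name="A" compartment="cell" initialConcentration="2"
               hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="B" name="B" compartment="cell" initialConcentration="0"
               hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k1" value="0.4" constant="true"/>
    </listOfParameters>
    %s
    <listOfReactions>
      <reaction id="r1" reversible="false" %s>
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">%s</math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', extra_model, reaction_attrs, kinetic_math)
}
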