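<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="T1">
    <listOfCompartments>
      <compartment id="cell" size="1"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="s1" compartment="cell" initialConcentration="1"/>
      <species id="s2" compartment="cell" initialConcentration="1"/>
      <species id="s3" compartment="cell" initialConcentration="1"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k1" value="1"/>
      <parameter id="v2" value="1"/>
      <parameter id="km2" value="1"/>
      <parameter id="k3" value="1"/>
      <parameter id="k4" value="1"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="net_s1" reversible="true">
        <listOfProducts>
          <speciesReference species="s1" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><apply><minus/><ci> k1 </ci><apply><divide/><apply><times/><apply><times/><ci> v2 </ci><ci> s3 </ci></apply><ci> s1 </ci></apply><apply><plus/><ci> km2 </ci><ci> s1 </ci></apply></apply></apply></math>
        </kineticLaw>
      </reaction>
      <reaction id="net_s2" reversible="true">
        <listOfProducts>
          <speciesReference species="s2" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><apply><minus/><apply><divide/><apply><times/><apply><times/><ci> v2 </ci><ci> s3 </ci></apply><ci> s1 </ci></apply><apply><plus/><ci> km2 </ci><ci> s1 </ci></apply></apply><apply><times/><ci> k3 </ci><ci> s2 </ci></apply></apply></math>
        </kineticLaw>
      </reaction>
      <reaction id="net_s3" reversible="true">
        <listOfProducts>
          <speciesReference species="s3" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><apply><minus/><apply><times/><ci> k3 </ci><ci> s2 </ci></apply><apply><times/><ci> k4 </ci><ci> s3 </ci></apply></apply></math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>

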